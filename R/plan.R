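#' Construct a management plan
#'
#' The 11-gene management genome applied identically in every simulated
#' season: nine ammonium-nitrate fertiliser application rates (kg N/ha,
#' each in `[0, 100]`; the first application is scheduled for 1 March with
#' subsequent applications at two-week intervals), a farm-yard manure (FYM)
#' amount (t/ha, `[0, 3]`), and the FYM timing in whole weeks before sowing
#' (integer 0--3).
#'
#' @param n_rates numeric vector of exactly 9 rates, kg N/ha.
#' @param fym_amount t/ha of FYM.
#' @param fym_weeks_before_sowing integer 0--3.
#' @return an object of class `management_plan`.
#' @export
management_plan <- function(n_rates, fym_amount = 0,
                            fym_weeks_before_sowing = 0L) {
  plan <- structure(
    list(n_rates = as.numeric(n_rates),
         fym_amount = as.numeric(fym_amount),
         fym_weeks_before_sowing = as.integer(round(fym_weeks_before_sowing))),
    class = "management_plan")
  validate_plan(plan)
  plan
}

#' Validate a management plan against the genome box bounds
#'
#' @param plan a [management_plan()].
#' @return the plan, invisibly; errors name the offending gene.
#' @export
validate_plan <- function(plan) {
  if (!inherits(plan, "management_plan")) stop("not a management_plan")
  r <- plan$n_rates
  if (length(r) != 9L) stop("n_rates must have exactly 9 values, got ",
                            length(r))
  bad <- which(!is.finite(r) | r < 0 | r > 100)
  if (length(bad)) stop("n_rates[", bad[1L], "] = ", r[bad[1L]],
                        " outside [0, 100]")
  f <- plan$fym_amount
  if (!is.finite(f) || f < 0 || f > 3)
    stop("fym_amount = ", f, " outside [0, 3]")
  w <- plan$fym_weeks_before_sowing
  if (is.na(w) || w < 0L || w > 3L)
    stop("fym_weeks_before_sowing = ", w, " outside {0, 1, 2, 3}")
  invisible(plan)
}

#' @export
print.management_plan <- function(x, ...) {
  cat("<management_plan> N rates (kg N/ha):",
      paste(formatC(x$n_rates, format = "fg", digits = 3), collapse = " "),
      sprintf("| FYM %.2f t/ha, %d wk before sowing\n",
              x$fym_amount, x$fym_weeks_before_sowing))
  invisible(x)
}

#' Genome box bounds for the management plan
#'
#' Lower/upper bounds and integer flags for the flattened 11-gene genome
#' (9 N rates, FYM amount, FYM timing). The single source of truth used by
#' the variation operators for bound repair.
#'
#' @return list with `lower`, `upper`, `integer` (logical), `names`.
#' @export
plan_bounds <- function() {
  list(lower = c(rep(0, 9), 0, 0),
       upper = c(rep(100, 9), 3, 3),
       integer = c(rep(FALSE, 10), TRUE),
       names = c(paste0("n", 1:9), "fym_amount", "fym_timing"))
}

#' Flatten a plan to its 11-number genome
#' @param plan a [management_plan()].
#' @return numeric vector of length 11.
#' @export
plan_genome <- function(plan) {
  c(plan$n_rates, plan$fym_amount, plan$fym_weeks_before_sowing)
}

#' Rebuild a plan from an 11-number genome
#' @param genome numeric vector of length 11.
#' @return a [management_plan()].
#' @export
plan_from_genome <- function(genome) {
  if (length(genome) != 11L) stop("genome must have 11 genes, got ",
                                  length(genome))
  management_plan(genome[1:9], genome[10], round(genome[11]))
}
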