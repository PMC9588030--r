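#' Classify a 2-hour window into the five clinical situations
#'
#' The five non-exclusive situations are:
#' \describe{
#'   \item{critical}{autoregulation critically impaired: mean PRx above 0.3
#'     for all CPP values (every CPP-bin mean PRx > 0.3, requiring at least
#'     3 bins) -- immediate intervention needed.}
#'   \item{intact}{autoregulation intact: window mean PRx < 0 -- no
#'     specific treatment necessary.}
#'   \item{cpp_guided}{the U-shape or LLCA/ULCA exist in PRx = f(CPP).}
#'   \item{abp_guided}{the U-shape or LLCA/ULCA exist in PRx = f(ABP).}
#'   \item{icp_guided}{ULCA exists in PRx = f(ICP).}
#' }
#' The primary situation is the first true flag in the precedence order
#' critical > intact > cpp_guided > abp_guided > icp_guided > none; all
#' flags are kept so no information is lost.
#'
#' @param fits Named list of `ushape_fit` objects for axes `cpp`, `abp`,
#'   `icp` (e.g. from [select_segments()]).
#' @param prx_series The window's PRx samples.
#' @param threshold Critical PRx threshold (default 0.3).
#' @param bin_width,min_count CPP binning used for the critical criterion.
#' @return An object of class `management_decision`: list with the five
#'   logical flags, `primary_situation`, and `missing_data`.
#' @export
classify_window <- function(fits, prx_series, threshold = 0.3,
                            bin_width = 5, min_count = 5) {
  prx <- prx_series$prx
  if (all(is.na(prx))) {
    return(structure(list(cpp_guided = FALSE, abp_guided = FALSE,
                          icp_guided = FALSE, intact = FALSE,
                          critical = FALSE,
                          primary_situation = "none", missing_data = TRUE),
                     class = "management_decision"))
  }
  cpp_bins <- bin_prx(prx_series, axis = "cpp", bin_width = bin_width,
                      min_count = min_count)
  critical <- nrow(cpp_bins) >= 3 && all(cpp_bins$mean_prx > threshold)
  intact <- mean(prx, na.rm = TRUE) < 0
  guided <- function(f, icp = FALSE) {
    if (is.null(f) || !f$fit_possible || !f$valid) return(FALSE)
    if (icp) !is.na(f$ulca)
    else !is.na(f$opt_value) || !is.na(f$llca) || !is.na(f$ulca)
  }
  flags <- list(cpp_guided = guided(fits$cpp),
                abp_guided = guided(fits$abp),
                icp_guided = guided(fits$icp, icp = TRUE),
                intact = intact, critical = critical)
  precedence <- c("critical", "intact", "cpp_guided", "abp_guided", "icp_guided")
  first <- precedence[unlist(flags[precedence])][1]
  structure(c(flags,
              list(primary_situation = if (is.na(first)) "none" else first,
                   missing_data = FALSE)),
            class = "management_decision")
}

#' Percentage-time yield report
#'
#' For a run of 2-hour windows, the percentage of windows (of all windows,
#' including those without usable data) in which each identification was
#' possible: the optimum per axis, optimum-or-limits per axis, their
#' unions, and the intact/critical statuses.
#'
#' @param decisions List of `management_decision` objects, one per window.
#' @param fits_list List (one element per window) of named lists of
#'   `ushape_fit` objects for axes `cpp`, `abp`, `icp`.
#' @return A named numeric vector of percentages in \[0, 100\] with entries
#'   `cppopt_identified`, `abpopt_identified`, `icp_ulca_identified`,
#'   `cpp_opt_or_limits`, `abp_opt_or_limits`, `abp_or_icp`, `cpp_or_abp`,
#'   `cpp_or_abp_or_icp`, `intact`, `critical`.
#' @export
yield_report <- function(decisions, fits_list) {
  stopifnot(length(decisions) == length(fits_list), length(decisions) >= 1)
  has <- function(f, what) {
    if (is.null(f) || !f$fit_possible) return(FALSE)
    switch(what,
           opt = f$valid && !is.na(f$opt_value),
           limits = f$valid && (!is.na(f$opt_value) || !is.na(f$llca) ||
                                  !is.na(f$ulca)),
           ulca = f$valid && !is.na(f$ulca))
  }
  per_window <- t(vapply(seq_along(decisions), function(i) {
    f <- fits_list[[i]]; d <- decisions[[i]]
    cpp_opt <- has(f$cpp, "opt")
    abp_opt <- has(f$abp, "opt")
    icp_ulca <- has(f$icp, "ulca")
    cpp_lim <- has(f$cpp, "limits")
    abp_lim <- has(f$abp, "limits")
    c(cppopt_identified = cpp_opt,
      abpopt_identified = abp_opt,
      icp_ulca_identified = icp_ulca,
      cpp_opt_or_limits = cpp_lim,
      abp_opt_or_limits = abp_lim,
      abp_or_icp = abp_lim || icp_ulca,
      cpp_or_abp = cpp_lim || abp_lim,
      cpp_or_abp_or_icp = cpp_lim || abp_lim || icp_ulca,
      intact = isTRUE(d$intact),
      critical = isTRUE(d$critical))
  }, logical(10)))
  100 * colMeans(per_window)
}
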