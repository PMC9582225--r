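`%||%` <- function(a, b) if (is.null(a)) b else a

# rbind data.frames with unequal columns, filling missing ones with NA.
rbind_fill <- function(dfs) {
  dfs <- dfs[!vapply(dfs, is.null, logical(1))]
  if (!length(dfs)) return(data.frame())
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
    d[cols]
  }))
}

#' Hill concentration-response curve
#'
#' Amplitude as a function of concentration,
#' `A(c) = A_max * c^n / (c^n + EC50^n)`. Used by the synthetic generator's
#' population amplitude model and by analytic cross-checks of the
#' concentration-coding analysis.
#'
#' @param conc Concentration(s), v/v fraction.
#' @param a_max Maximal amplitude (dF/F %).
#' @param ec50 Half-maximal concentration, same units as `conc`.
#' @param hill_n Hill coefficient.
#' @return Amplitude(s) on the scale of `a_max`.
#' @export
hill_amplitude <- function(conc, a_max, ec50, hill_n) {
  a_max * conc^hill_n / (conc^hill_n + ec50^hill_n)
}
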