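#' MAP state/duration decode
#'
#' Per-trial maximum a posteriori estimate over the smoothed joint posterior
#' of state and remaining duration: \eqn{(\hat S_t, \hat\tau_t) =
#' \mathrm{argmax}_{m,d}} of the `[trial, state, duration]` table.  Exact
#' ties are broken toward the smaller state index, then the smaller
#' duration.
#'
#' @param x an [HSMMFit-class], a completed [FBCache-class] (the smoothed
#'   joint posterior \eqn{\alpha_{t|T}} is decoded), or a bare numeric array
#'   indexed `[trial, state, duration]`.
#' @return data.frame with columns `trial`, `state` (labels 0/1, i.e. state
#'   index minus one), `tau` (decoded remaining duration), and `pAttended`
#'   (smoothed probability of the attended state, when available).
#' @export
mapDecode <- function(x) {
  post <- NULL
  if (is(x, "HSMMFit")) {
    post <- x@posterior@alphaSmooth
    gam <- x@posterior@gammaSmooth
  } else if (is(x, "FBCache")) {
    if (length(x@alphaSmooth) == 0L)
      stop("cache has no smoothed posterior; run smoothPosteriors()")
    post <- x@alphaSmooth
    gam <- x@gammaSmooth
  } else if (is.array(x) && length(dim(x)) == 3L) {
    post <- x
    gam <- NULL
  } else stop("cannot decode object of class ", class(x)[1L])

  Tn <- dim(post)[1L]
  M <- dim(post)[2L]
  D <- dim(post)[3L]
  st <- integer(Tn)
  tau <- integer(Tn)
  for (t in seq_len(Tn)) {
    tab <- matrix(post[t, , ], M, D)
    hit <- which(tab == max(tab), arr.ind = TRUE)
    # ties: smaller state index first, then smaller duration
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    st[t] <- hit[1L, 1L] - 1L
    tau[t] <- hit[1L, 2L]
  }
  out <- data.frame(trial = seq_len(Tn), state = st, tau = tau)
  if (!is.null(gam)) out$pAttended <- gam[, 2L]
  out
}
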