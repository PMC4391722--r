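#' Read a trials CSV
#'
#' Parses a comma-separated file with header columns `trial` (1-based,
#' strictly increasing integers), `y` (0/1) and `z` (positive decimal);
#' extra columns are ignored.  Parse errors cite the offending line number
#' (header = line 1).
#'
#' @param path file path.
#' @return A validated [TrialSequence-class].
#' @export
readTrials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  if (nrow(df) < 1L) stop("no trials in ", path)
  line <- function(i) i + 1L  # data row i sits on file line i + 1
  tr <- df$trial
  bad <- which(tr != seq_along(tr))
  if (length(bad))
    stop(sprintf("trial index must be 1-based and strictly increasing (line %d)",
                 line(bad[1L])))
  bad <- which(!df$y %in% c(0, 1))
  if (length(bad))
    stop(sprintf("y must be 0 or 1 (line %d)", line(bad[1L])))
  bad <- which(!is.finite(df$z) | df$z <= 0)
  if (length(bad))
    stop(sprintf("z must be a positive number (line %d)", line(bad[1L])))
  TrialSequence(df$y, df$z)
}

#' Write a trials CSV
#'
#' Writes `trial,y,z` (plus `state,tau` when a ground-truth path is
#' supplied), latencies at full precision, so that [readTrials()]
#' round-trips bit-identically.
#'
#' @param seq a [TrialSequence-class].
#' @param path output path.
#' @param truth optional [LatentPath-class] of the same length.
#' @return `path`, invisibly.
#' @export
writeTrials <- function(seq, path, truth = NULL) {
  df <- data.frame(trial = seq_len(nTrials(seq)), y = seq@y,
                   z = format(seq@z, digits = 17, trim = TRUE,
                              scientific = FALSE))
  if (!is.null(truth)) {
    if (nTrials(truth) != nTrials(seq))
      stop("truth path length must match the sequence")
    df$state <- states(truth)
    df$tau <- sojourns(truth)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write model parameters to YAML
#'
#' Flat structured text with keys `pi`, `A` (row-major), `P` (row-major),
#' `bern`, `mu`, `sigma`, `dmax`, `duration_model` (and `geom_rate` for the
#' geometric model); numbers keep at least 12 significant digits.
#'
#' @param params an [HSMMParameters-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeParams <- function(params, path) {
  num <- function(x) as.numeric(signif(x, 15))
  obj <- list(pi = num(params@pi),
              A = num(as.vector(t(params@A))),
              P = num(as.vector(t(params@Pdur))),
              bern = num(params@bern),
              mu = num(params@mu),
              sigma = num(params@sigma),
              dmax = params@dMax,
              duration_model = params@durationModel)
  if (params@durationModel == "geometric")
    obj$geom_rate <- num(params@geomRate)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Read model parameters from YAML
#'
#' Inverse of [writeParams()].
#'
#' @param path YAML file path.
#' @return A validated [HSMMParameters-class].
#' @export
readParams <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- yaml::read_yaml(path)
  need <- c("pi", "A", "P", "bern", "mu", "sigma", "dmax", "duration_model")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("missing key(s) in ", path, ": ", paste(miss, collapse = ", "))
  M <- length(obj$pi)
  HSMMParameters(pi = obj$pi,
                 A = matrix(obj$A, M, M, byrow = TRUE),
                 Pdur = matrix(obj$P, M, obj$dmax, byrow = TRUE),
                 bern = obj$bern, mu = obj$mu, sigma = obj$sigma,
                 dMax = obj$dmax, durationModel = obj$duration_model,
                 geomRate = if (is.null(obj$geom_rate)) numeric(0)
                            else obj$geom_rate)
}

#' Write a decode CSV
#'
#' One row per trial: `trial`, observed `y` and `z`, decoded state `S_hat`,
#' decoded remaining duration `tau_hat`, and the smoothed probability of
#' the attended state `gamma_attended`.
#'
#' @param seq the decoded [TrialSequence-class].
#' @param decode the data.frame from [mapDecode()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDecode <- function(seq, decode, path) {
  df <- data.frame(trial = decode$trial, y = seq@y,
                   z = format(seq@z, digits = 17, trim = TRUE,
                              scientific = FALSE),
                   S_hat = decode$state, tau_hat = decode$tau,
                   gamma_attended = if (!is.null(decode$pAttended))
                     format(decode$pAttended, digits = 12, trim = TRUE)
                   else NA)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
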