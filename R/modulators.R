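#' Parametric modulators for connectivity modelling
#'
#' Builds the two modulatory input functions consumed by a connectivity
#' (effective-connectivity / DCM-style) backend from a fitted combined
#' belief trajectory: a boxcar over every no-think trial whose height is
#' the predicted intrusion belief, and a boxcar restricted to intrusion
#' trials whose height is the positive prediction error
#' (`PE = y - muhat > 0`). Negative prediction errors carry no reactive
#' control demand and are excluded; modulator heights are not
#' orthogonalised and, by default, not mean-centred.
#'
#' @param muhat per-trial combined beliefs in (0, 1) (e.g.
#'   `fit$trajectory$muhat` of the winning combined model).
#' @param y per-trial binary outcomes.
#' @param onsets trial onset times in seconds, one per trial.
#' @param duration boxcar duration in seconds (cue presentation, default
#'   3; set 0 for stick functions).
#' @param mean_center mean-centre the two height columns (off by default,
#'   preserving the raw computational quantities).
#' @return data frame of class `tnt_modulators` with one row per no-think
#'   trial: `onset`, `duration`, `trial_type` (`"intrusion"` /
#'   `"nonintrusion"`), `belief` (all trials) and `pe_pos` (intrusion
#'   trials only, NA elsewhere).
#' @export
build_modulators <- function(muhat, y, onsets, duration = 3,
                             mean_center = FALSE) {
  y <- .check_binary(y)
  n <- length(y)
  if (length(muhat) != n)
    stop("trajectory and outcomes are misaligned")
  if (length(onsets) != n || anyNA(onsets))
    stop("every trial needs an onset time")
  stopifnot(all(muhat > 0 & muhat < 1))
  pe <- pe_positive(muhat, y)
  belief <- muhat
  if (mean_center) {
    belief <- belief - mean(belief)
    pe <- pe - mean(pe, na.rm = TRUE)
  }
  out <- data.frame(onset = onsets, duration = duration,
                    trial_type = ifelse(y == 1, "intrusion",
                                        "nonintrusion"),
                    belief = belief, pe_pos = pe,
                    stringsAsFactors = FALSE)
  class(out) <- c("tnt_modulators", "data.frame")
  out
}

#' Read and write event/trajectory tables
#'
#' Plain-text tab-separated exchange format (events tables in the style of
#' BIDS events.tsv). Numeric columns are written with 15 significant
#' digits so that a write/read round trip reproduces the values exactly at
#' double precision; missing values are written as `n/a`.
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `read_events()` returns a data frame; `write_events()` returns
#'   `path` invisibly.
#' @export
write_events <- function(x, path) {
  fmt <- as.data.frame(lapply(x, function(col) {
    if (is.numeric(col)) {
      out <- formatC(col, digits = 15, format = "g")
      out[is.na(col)] <- "n/a"
      out
    } else {
      out <- as.character(col)
      out[is.na(out)] <- "n/a"
      out
    }
  }), stringsAsFactors = FALSE)
  names(fmt) <- names(x)
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  read.delim(path, na.strings = "n/a", stringsAsFactors = FALSE)
}

#' Read and write log-evidence matrices
#'
#' Subjects x models tab-separated matrix with a header row of model
#' labels, as consumed by [rfx_bms()].
#'
#' @param L numeric matrix (subjects x models).
#' @param path file path.
#' @export
write_evidence <- function(L, path) {
  write_events(as.data.frame(L), path)
}

#' @rdname write_evidence
#' @export
read_evidence <- function(path) {
  as.matrix(read_events(path))
}
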