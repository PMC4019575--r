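# CSV readers for per-beam backscatter samples and ground-truth observations.

#' The seven benthic biota class labels
#'
#' Mixed Brown algae (MB), Invertebrates (INV), Mixed Red algae and
#' Invertebrates (MRI), No Visible Biota (NVB), Mixed Brown algae and
#' Invertebrates (MBI), Mixed Brown algae and Mixed Red algae (MBMR), Mixed
#' Green algae and Invertebrates (MGI).
#' @export
habitat_classes <- c("MB", "INV", "MRI", "NVB", "MBI", "MBMR", "MGI")

.require_cols <- function(dt, cols, what) {
  miss <- setdiff(cols, names(dt))
  if (length(miss))
    stop(sprintf("%s CSV is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")))
}

#' Read per-beam backscatter samples
#'
#' Expects a CSV with header columns `ping_id, beam_id, x, y, depth, angle,
#' level` (plus optional `line_id`, defaulting to 1). Rows violating the
#' sample invariants (angle outside \[0, 90\] after optional folding,
#' non-finite level, duplicate `(line_id, ping_id, beam_id)`) are dropped and
#' the count reported via a message and the `"rejected"` attribute.
#'
#' @param path CSV path.
#' @param fold_angles if `TRUE` (default) signed incidence angles are folded
#'   to unsigned (`abs`); if `FALSE` negative angles are rejected.
#' @return `data.table` of samples, attribute `rejected` = number of dropped
#'   rows.
#' @export
read_samples <- function(path, fold_angles = TRUE) {
  dt <- fread(path)
  .require_cols(dt, c("ping_id", "beam_id", "x", "y", "depth", "angle", "level"),
                "backscatter sample")
  if (!"line_id" %in% names(dt)) dt[, line_id := 1L]
  n0 <- nrow(dt)
  if (fold_angles) dt[, angle := abs(angle)]
  ok <- is.finite(dt$angle) & dt$angle >= 0 & dt$angle <= 90 &
    is.finite(dt$level) & is.finite(dt$x) & is.finite(dt$y)
  ok[ok] <- !duplicated(dt[ok, .(line_id, ping_id, beam_id)])
  dt <- dt[ok]
  rejected <- n0 - nrow(dt)
  if (rejected > 0)
    message(sprintf("read_samples: rejected %d row(s) violating sample invariants", rejected))
  setattr(dt, "rejected", rejected)
  dt[]
}

#' Read ground-truth habitat observations
#'
#' Expects CSV columns `x, y, label` and optionally `split` (`train`/`test`).
#'
#' @param path CSV path.
#' @return `data.table` with columns `x`, `y`, `label`, `split` (NA when not
#'   yet assigned).
#' @export
read_ground_truth <- function(path) {
  dt <- fread(path)
  .require_cols(dt, c("x", "y", "label"), "ground-truth")
  bad <- setdiff(unique(dt$label), habitat_classes)
  if (length(bad))
    stop(sprintf("unknown habitat label(s) %s; valid labels are: %s",
                 paste(sQuote(bad), collapse = ", "),
                 paste(habitat_classes, collapse = ", ")))
  if (!"split" %in% names(dt)) dt[, split := NA_character_]
  if (any(!is.na(dt$split) & !dt$split %in% c("train", "test")))
    stop("split column may only contain 'train' or 'test'")
  dt[]
}

#' Write backscatter samples / ground truth to CSV
#' @param dt a `data.table` (samples or ground truth).
#' @param path destination CSV.
#' @export
write_table_csv <- function(dt, path) {
  fwrite(dt, path)
  invisible(path)
}
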