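# Trauma scores: ISS, NISS and the coded Revised Trauma Score.
#
# The coding tables below are the standard published ones; they are external
# reference values, not tuned by this package.

# RTS component weights (coded GCS, systolic BP, respiratory rate).
RTS_WEIGHTS <- c(gcs = 0.9368, sbp = 0.7326, rr = 0.2908)

#' Map physiological values to their standard 0-4 RTS codes
#'
#' @param gcs Glasgow Coma Scale, integer 3-15.
#' @param sbp systolic blood pressure, mmHg.
#' @param rr respiratory rate, breaths/min.
#' @return named integer vector with elements `gcs`, `sbp`, `rr`.
#' @export
rts_codes <- function(gcs, sbp, rr) {
  gc <- if (gcs >= 13) 4L else if (gcs >= 9) 3L else if (gcs >= 6) 2L else if (gcs >= 4) 1L else 0L
  sc <- if (sbp > 89) 4L else if (sbp >= 76) 3L else if (sbp >= 50) 2L else if (sbp >= 1) 1L else 0L
  rc <- if (rr >= 10 && rr <= 29) 4L else if (rr > 29) 3L else if (rr >= 6) 2L else if (rr >= 1) 1L else 0L
  c(gcs = gc, sbp = sc, rr = rc)
}

#' Injury Severity Score
#'
#' Sum of squares of the three highest AIS severities drawn from distinct
#' body regions; any AIS-6 injury sets the score to the maximum of 75.
#' The region partition is the package's nine-value anatomical enumeration
#' (see [injury()]); each enumerated region counts as distinct.
#'
#' @param injuries list of [injury()] objects (possibly empty).
#' @return integer in \[0, 75\].
#' @export
#' @examples
#' compute_iss(list(injury("head", 3), injury("thorax", 3),
#'                  injury("lower-extremity", 2)))  # 22
compute_iss <- function(injuries) {
  if (length(injuries) == 0) return(0L)
  ais <- vapply(injuries, function(i) i$ais, integer(1))
  if (any(ais == 6L)) return(75L)
  region <- vapply(injuries, function(i) i$body_region, character(1))
  worst <- tapply(ais, region, max)
  top <- sort(worst, decreasing = TRUE)[seq_len(min(3L, length(worst)))]
  as.integer(sum(top^2))
}

#' New Injury Severity Score
#'
#' Sum of squares of the three highest AIS severities regardless of body
#' region; always at least the ISS.
#'
#' @inheritParams compute_iss
#' @return integer in \[0, 75\].
#' @export
compute_niss <- function(injuries) {
  if (length(injuries) == 0) return(0L)
  ais <- vapply(injuries, function(i) i$ais, integer(1))
  if (any(ais == 6L)) return(75L)
  top <- sort(ais, decreasing = TRUE)[seq_len(min(3L, length(ais)))]
  as.integer(sum(top^2))
}

#' Coded Revised Trauma Score
#'
#' Each physiological parameter is mapped to its standard 0-4 code and the
#' codes are combined with the published weights 0.9368 (GCS), 0.7326
#' (systolic BP) and 0.2908 (respiratory rate), giving a score in
#' \[0, 7.8408\].
#'
#' @param snapshot a [physiology_snapshot()].
#' @return numeric score.
#' @export
compute_rts <- function(snapshot) {
  codes <- rts_codes(snapshot$gcs, snapshot$sbp, snapshot$rr)
  unname(sum(RTS_WEIGHTS * codes))
}
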