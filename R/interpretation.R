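#' Assign segments to respiration phases
#'
#' Each segment's receptive-field time span is compared against the annotated
#' inspiration and expiration intervals; the segment is assigned to the phase
#' overlapping the larger share of its span. Segments overlapping no annotated
#' interval (or tied exactly) are left unassigned and excluded from the MAD
#' means.
#'
#' @param outputs A `segment_outputs` from [predict_clip] (or any list with a
#'   `spans` matrix).
#' @param ann A [phase_annotation] (non-empty).
#' @return List with integer index vectors `inspiration` and `expiration`.
#' @export
assign_segments_to_phases <- function(outputs, ann) {
  if (nrow(ann) == 0L) stop("annotation is empty")
  spans <- outputs$spans
  overlap_with <- function(phase) {
    iv <- ann[ann$phase == phase, , drop = FALSE]
    vapply(seq_len(nrow(spans)), function(i) {
      sum(pmax(0, pmin(spans[i, 2L], iv$end) - pmax(spans[i, 1L], iv$start)))
    }, numeric(1))
  }
  o_in <- overlap_with("inspiration")
  o_out <- overlap_with("expiration")
  list(inspiration = which(o_in > o_out),
       expiration = which(o_out > o_in))
}

#' Mean-Attention Difference (MAD)
#'
#' Quantifies whether the model attends more to expiration than inspiration.
#' With \eqn{\alpha_{in}} and \eqn{\alpha_{out}} the unweighted means of the
#' attention values \eqn{g(x_i)} over segments assigned to inspiration and
#' expiration,
#' \deqn{MAD = (\alpha_{out} - \alpha_{in}) / \max(\alpha_{out}, \alpha_{in}),}
#' so \eqn{MAD \in [-1, 1]}: positive means the model focuses on expiration,
#' negative on inspiration. MAD is invariant to rescaling of the attention
#' values. At least one segment must fall in each phase.
#'
#' @param outputs A `segment_outputs` from [predict_clip].
#' @param ann A [phase_annotation].
#' @return An object of class `mad_result`: list with `alpha_in`,
#'   `alpha_out`, `mad`, `n_in`, `n_out`.
#' @export
compute_mad <- function(outputs, ann) {
  idx <- assign_segments_to_phases(outputs, ann)
  if (!length(idx$inspiration) || !length(idx$expiration))
    stop("undefined MAD: need at least one segment in each phase")
  a_in <- mean(outputs$g[idx$inspiration])
  a_out <- mean(outputs$g[idx$expiration])
  structure(list(alpha_in = a_in, alpha_out = a_out,
                 mad = (a_out - a_in) / max(a_out, a_in),
                 n_in = length(idx$inspiration), n_out = length(idx$expiration)),
            class = "mad_result")
}

#' @export
print.mad_result <- function(x, ...) {
  cat(sprintf("<mad_result> MAD = %+.3f (alpha_in %.4g over %d, alpha_out %.4g over %d)\n",
              x$mad, x$alpha_in, x$n_in, x$alpha_out, x$n_out))
  invisible(x)
}

#' Per-recording MAD values over a cohort
#'
#' Runs the model on every annotated recording and computes its MAD.
#' Recordings whose MAD is undefined (a phase with no assigned segment) are
#' skipped.
#'
#' @param model A trained `segment_model`.
#' @param patients List of [patient_record]s (with annotations).
#' @param spec_cfg A [spectrogram_config].
#' @return Data frame with patient_id, site, diagnosis, mad.
#' @export
cohort_mad <- function(model, patients, spec_cfg = spectrogram_config()) {
  rows <- list()
  for (p in patients) {
    for (site in names(p$annotations %||% list())) {
      ann <- p$annotations[[site]]
      if (is.null(ann) || nrow(ann) == 0L) next
      out <- predict_clip(p$clips[[site]], model, spec_cfg)
      md <- tryCatch(compute_mad(out, ann), error = function(e) NULL)
      if (is.null(md)) next
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p$patient_id, site = site, diagnosis = p$diagnosis,
        mad = md$mad, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(patient_id = character(), site = character(),
                      diagnosis = character(), mad = numeric()))
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize MAD distributions per diagnosis
#'
#' Median, adjusted Fisher-Pearson sample skewness and count of the MAD values
#' in each diagnostic group. Groups with fewer than 3 recordings get `NA`
#' skewness (a single recording has no distribution); empty groups are skipped
#' with a warning.
#'
#' @param mad_df Data frame from [cohort_mad] (columns diagnosis, mad).
#' @return Data frame with diagnosis, n, median_mad, skewness.
#' @export
mad_cohort_summary <- function(mad_df) {
  rows <- list()
  for (dg in ausc_diagnoses) {
    v <- mad_df$mad[mad_df$diagnosis == dg]
    if (!length(v)) {
      warning("no MAD values for group '", dg, "'; skipped")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      diagnosis = dg, n = length(v), median_mad = stats::median(v),
      skewness = if (length(v) >= 3L) e1071::skewness(v, type = 2L) else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Export an attention overlay
#'
#' Writes a CSV pairing segment times with attention and prediction values and
#' the assigned phase, and (optionally) a PNG showing the log-mel spectrogram
#' with the attention curve and the phase intervals selected by the MAD sign:
#' inspiration intervals when MAD < 0, expiration intervals when MAD > 0.
#'
#' @param outputs A `segment_outputs` from [predict_clip].
#' @param spec The spectrogram of the same clip.
#' @param ann The clip's [phase_annotation].
#' @param csv Output CSV path.
#' @param png Optional output PNG path (`NULL` to skip plotting).
#' @return The MAD result, invisibly.
#' @export
export_overlay <- function(outputs, spec, ann, csv, png = NULL) {
  clip_dur <- (ncol(spec$values) - 1L) / spec$frame_rate
  if (abs(clip_dur - outputs$geometry$duration) > outputs$geometry$stride_sec)
    stop("alignment error: spectrogram and outputs cover different durations")
  md <- compute_mad(outputs, ann)
  idx <- assign_segments_to_phases(outputs, ann)
  phase <- rep("unassigned", length(outputs$g))
  phase[idx$inspiration] <- "inspiration"
  phase[idx$expiration] <- "expiration"
  mid <- rowMeans(outputs$spans)
  utils::write.csv(data.frame(time = mid, attention = outputs$g,
                              prediction = outputs$p, phase = phase),
                   csv, row.names = FALSE, quote = FALSE)
  if (!is.null(png)) {
    shown <- if (md$mad < 0) "inspiration" else "expiration"
    iv <- ann[ann$phase == shown, , drop = FALSE]
    grDevices::png(png, width = 1200, height = 500)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(4, 4, 2, 4))
    graphics::image(x = spec$frame_times, y = seq_len(nrow(spec$values)),
                    z = t(spec$values), col = grDevices::hcl.colors(64, "inferno"),
                    xlab = "time (s)", ylab = "mel band",
                    main = sprintf("attention overlay (MAD = %+.2f, %s phases shown)",
                                   md$mad, shown))
    if (nrow(iv))
      graphics::rect(iv$start, 0.5, iv$end, nrow(spec$values) + 0.5,
                     border = "white", lty = 2)
    att <- outputs$g / max(outputs$g) * nrow(spec$values)
    graphics::lines(mid, att, col = "cyan", lwd = 2)
    graphics::axis(4, at = c(0, nrow(spec$values)),
                   labels = signif(c(0, max(outputs$g)), 2))
    graphics::mtext("attention g(x_i)", side = 4, line = 2)
  }
  invisible(md)
}
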