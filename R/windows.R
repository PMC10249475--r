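# Analysis constants: scalp regions of interest and the fixed analysis
# windows, all times in milliseconds relative to the demarcation event
# (button press for reversal epochs, artificial marker for non-reversal
# epochs). Windows are half-open [start, end).

#' Electrode pairs forming each region of interest
#'
#' Each region of interest (ROI) is the average of one homologous electrode
#' pair: frontal F = F3/F4, central C = C3/C4, parietal P = P3/P4,
#' occipital O = O1/O2.
#'
#' @return Named list of length-2 character vectors.
#' @examples
#' roi_pairs()$O
#' @export
roi_pairs <- function() {
  list(F = c("F3", "F4"), C = c("C3", "C4"),
       P = c("P3", "P4"), O = c("O1", "O2"))
}

#' Analysis time windows for a condition
#'
#' Endogenous reversals use a pre-reversal window of -950 to -650 ms and a
#' reversal window of -350 to -50 ms relative to the button press. For
#' exogenous (stimulus-driven) reversals both windows slide 100 ms towards
#' the press (-850 to -550 and -250 to +50 ms) to account for the earlier,
#' steeper time course of the stimulus-driven alpha response. The baseline
#' window is the 500 ms preceding the artificial marker of non-reversal
#' epochs and is identical for both conditions.
#'
#' @param condition `"endogenous"` or `"exogenous"`.
#' @return Named list with `pre_reversal`, `reversal` and `baseline`,
#'   each `c(start, end)` in ms; windows are half-open `[start, end)`.
#' @examples
#' analysis_windows("endogenous")
#' @export
analysis_windows <- function(condition = c("endogenous", "exogenous")) {
  condition <- match.arg(condition)
  shift <- if (condition == "exogenous") 100 else 0
  list(pre_reversal = c(-950, -650) + shift,
       reversal     = c(-350, -50) + shift,
       baseline     = c(-500, 0))
}

#' @rdname analysis_windows
#' @export
baseline_window <- function() c(-500, 0)

# Default analyzed channel montage (10-20 positions; temporal leads not used).
#' Default analyzed EEG channels
#' @return Character vector of the eight analyzed 10-20 electrode labels.
#' @export
default_channels <- function() c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2")
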