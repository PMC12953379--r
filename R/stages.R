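#' Sleep-stage vocabulary
#'
#' Four scoreable classes (wake, merged N1/N2 light sleep, N3 slow-wave
#' sleep, REM) plus two bookkeeping tokens: `ARTIFACT` marks epochs an
#' expert scorer declared unscorable, and `PAD` marks epochs appended by
#' windowing to reach a fixed model input length. Only the four scoreable
#' classes are ever predicted by the model; `ARTIFACT` and `PAD` are
#' excluded from the loss and from all agreement metrics.
#'
#' @format Character vectors of stage tokens.
#' @name stage-vocabulary
NULL

#' @rdname stage-vocabulary
#' @export
SLEEP_STAGES <- c("WAKE", "N1N2", "N3", "REM")

#' @rdname stage-vocabulary
#' @export
STAGE_TOKENS <- c("WAKE", "N1N2", "N3", "REM", "ARTIFACT", "PAD")

#' Seconds per scoring epoch (fixed by convention).
#' @export
EPOCH_SEC <- 30

#' Construct a hypnogram
#'
#' A hypnogram is a character vector of per-epoch stage tokens with class
#' `hypnogram`. Epochs are 30 s; indices are 0-based in all file formats
#' and 1-based inside R, like any R vector.
#'
#' @param stages Character vector of tokens from [STAGE_TOKENS].
#' @return Object of class `hypnogram`.
#' @export
hypnogram <- function(stages) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), STAGE_TOKENS)
  if (length(bad) > 0) {
    stop("unknown stage token(s): ", paste(bad, collapse = ", "),
         "; accepted tokens are: ", paste(STAGE_TOKENS, collapse = ", "))
  }
  structure(stages, class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = STAGE_TOKENS))
  cat(sprintf("<hypnogram> %d epochs (%.1f h)\n",
              length(x), length(x) * EPOCH_SEC / 3600))
  print(tab)
  invisible(x)
}

#' @export
`[.hypnogram` <- function(x, i, ...) hypnogram(unclass(x)[i])

#' Is an epoch scoreable (contributes to loss and metrics)?
#' @param stages Character vector of stage tokens.
#' @return Logical vector, `TRUE` where the token is one of the four classes.
#' @export
is_scoreable <- function(stages) {
  as.character(stages) %in% SLEEP_STAGES
}

#' Integer class index of each stage (WAKE=1, N1N2=2, N3=3, REM=4;
#' `NA` for ARTIFACT/PAD).
#' @param stages Character vector of stage tokens.
#' @export
stage_index <- function(stages) {
  match(as.character(stages), SLEEP_STAGES)
}
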