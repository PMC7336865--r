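#' Stage-of-change coding
#'
#' The model works on four ordered stages of behaviour change:
#' precontemplation (1) < contemplation (2) < preparation (3) < action (4).
#' "Forward" movement is towards a higher code, "backward" towards a lower
#' one; action is absorbing (quitting is recorded once and never reversed
#' within the observation window).
#'
#' @return `stage_levels()` returns the four canonical labels in order.
#' @export
stage_levels <- function() {
  c("precontemplation", "contemplation", "preparation", "action")
}

#' @rdname stage_levels
#' @param x integer codes 1-4, or stage labels (case-insensitive); mixed
#'   vectors are allowed.
#' @return `stage_code()` returns an integer vector in 1..4.
#' @export
stage_code <- function(x) {
  if (length(x) == 0L) return(integer(0))
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    bad <- !is.finite(x) | x != as.integer(x) | x < 1 | x > 4
    if (any(bad)) {
      stop("unknown stage code(s): ", paste(unique(x[bad]), collapse = ", "),
           call. = FALSE)
    }
    return(as.integer(x))
  }
  lab <- tolower(trimws(as.character(x)))
  out <- match(lab, stage_levels())
  num <- match(lab, as.character(1:4))
  out[is.na(out)] <- num[is.na(out)]
  if (anyNA(out)) {
    stop("unknown stage label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  as.integer(out)
}

#' @rdname stage_levels
#' @param code integer stage codes in 1..4.
#' @return `stage_label()` returns the corresponding labels.
#' @export
stage_label <- function(code) {
  stage_levels()[stage_code(code)]
}

# direction of a move: +1 forward, -1 backward, 0 stay
stage_direction <- function(from, to) {
  sign(stage_code(to) - stage_code(from))
}
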