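#' Construct an affect state
#'
#' An affect state is a point on the circumplex model of affect: a pair of
#' continuous coordinates, valence (pleasantness) and arousal (activation),
#' each in \[0, 1\]. Every per-bar musical decision in the generator is a
#' function of the current affect state.
#'
#' Out-of-range coordinates are rejected with an error by default (loud
#' failure on user error in batch input). When `clamp = TRUE` -- the mode
#' used for streaming input, where slightly out-of-range values can arise
#' from sensor noise -- coordinates are clamped into \[0, 1\] instead.
#'
#' @param valence Numeric scalar, pleasantness coordinate.
#' @param arousal Numeric scalar, activation coordinate.
#' @param clamp If `TRUE`, clamp out-of-range values into \[0, 1\];
#'   if `FALSE` (default), reject them with an error.
#' @return An object of class `affect_state`: a list with numeric fields
#'   `valence` and `arousal`.
#' @examples
#' affect_state(0.25, 0.75)
#' affect_state(1.2, -0.1, clamp = TRUE)  # -> (1, 0)
#' @export
affect_state <- function(valence, arousal, clamp = FALSE) {
  stopifnot(is.numeric(valence), length(valence) == 1L, is.finite(valence),
            is.numeric(arousal), length(arousal) == 1L, is.finite(arousal))
  if (clamp) {
    valence <- min(max(valence, 0), 1)
    arousal <- min(max(arousal, 0), 1)
  } else if (valence < 0 || valence > 1 || arousal < 0 || arousal > 1) {
    stop("affect coordinates must lie in [0, 1]: got valence = ", valence,
         ", arousal = ", arousal, call. = FALSE)
  }
  structure(list(valence = valence, arousal = arousal), class = "affect_state")
}

#' @export
print.affect_state <- function(x, ...) {
  cat(sprintf("<affect_state> valence = %.3f, arousal = %.3f\n",
              x$valence, x$arousal))
  invisible(x)
}

as_affect_state <- function(x, clamp = FALSE) {
  if (inherits(x, "affect_state")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(affect_state(x[[1]], x[[2]], clamp = clamp))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an affect state", call. = FALSE)
}

#' Construct an affect trajectory
#'
#' A trajectory supplies one affect state per bar. Accepted inputs:
#' * a single [affect_state()] or numeric `c(valence, arousal)` -- a constant
#'   trajectory that repeats its state for every bar;
#' * a data frame with columns `valence` and `arousal` (optionally `bar`):
#'   with a `bar` column the trajectory is a step function holding each row's
#'   state from its bar onwards; without one, row `b` drives bar `b`, the last
#'   row persisting past the end;
#' * a path to a CSV file with those columns, or a JSON file holding a list of
#'   `{bar, valence, arousal}` (or `{valence, arousal}`) records;
#' * a function `f(bar)` returning `c(valence, arousal)` -- the streaming
#'   contract. Streaming values are clamped into \[0, 1\] (sensor-noise
#'   tolerance); file and data-frame input is validated strictly and rejected
#'   when out of range.
#'
#' @param x Trajectory specification (see Details).
#' @return An object of class `affect_trajectory`.
#' @seealso [state_at()]
#' @export
affect_trajectory <- function(x) {
  if (inherits(x, "affect_trajectory")) return(x)
  if (is.function(x)) {
    return(structure(list(type = "stream", fun = x), class = "affect_trajectory"))
  }
  if (inherits(x, "affect_state") || (is.numeric(x) && length(x) == 2L)) {
    st <- as_affect_state(x)
    return(structure(list(type = "constant", state = st), class = "affect_trajectory"))
  }
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("trajectory file not found: ", x, call. = FALSE)
    x <- if (grepl("\\.json$", x, ignore.case = TRUE)) {
      as.data.frame(jsonlite::fromJSON(x))
    } else {
      utils::read.csv(x)
    }
  }
  if (is.data.frame(x)) {
    if (!all(c("valence", "arousal") %in% names(x)))
      stop("trajectory table needs columns 'valence' and 'arousal'", call. = FALSE)
    if (nrow(x) < 1L) stop("empty trajectory table", call. = FALSE)
    if (any(x$valence < 0 | x$valence > 1 | x$arousal < 0 | x$arousal > 1))
      stop("trajectory contains affect values outside [0, 1]", call. = FALSE)
    if ("bar" %in% names(x)) x <- x[order(x$bar), , drop = FALSE]
    return(structure(list(type = "table", data = x), class = "affect_trajectory"))
  }
  stop("cannot interpret trajectory input", call. = FALSE)
}

#' Affect state driving a given bar
#'
#' @param trajectory An [affect_trajectory()].
#' @param bar Bar number (1-based).
#' @return An [affect_state()].
#' @export
state_at <- function(trajectory, bar) {
  trajectory <- affect_trajectory(trajectory)
  stopifnot(is.numeric(bar), length(bar) == 1L, bar >= 1)
  switch(trajectory$type,
    constant = trajectory$state,
    stream = as_affect_state(trajectory$fun(bar), clamp = TRUE),
    table = {
      d <- trajectory$data
      i <- if ("bar" %in% names(d)) {
        j <- which(d$bar <= bar)
        if (length(j) == 0L) 1L else max(j)
      } else {
        min(as.integer(bar), nrow(d))
      }
      affect_state(d$valence[[i]], d$arousal[[i]])
    })
}

#' @export
print.affect_trajectory <- function(x, ...) {
  cat("<affect_trajectory> type:", x$type, "\n")
  invisible(x)
}
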