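#' Build a schedule of recurrent drought events
#'
#' Places `n_events` drought events of `event_length` generations each at
#' regular intervals within a horizon of `G` generations. Event `e`
#' (1-indexed) starts at generation `round(e * G / (n_events + 1))`, a
#' symmetric convention that leaves room before the first and after the last
#' event. Generation indices are 1-based; drought fitness applies to
#' reproduction *into* a listed generation.
#'
#' @param G Number of simulated generations (horizon).
#' @param n_events Number of drought events, 1 to 4 in the study design
#'   (any positive count is accepted as long as events fit).
#' @param event_length Length of each event in generations (2, 3 or 4 in the
#'   study design; any positive length is accepted).
#'
#' @return An integer vector of drought generation indices (class
#'   `drought_schedule`), with attributes `G`, `n_events` and `event_length`.
#'
#' @examples
#' build_drought_schedule(50, 1, 2) # generations 25, 26
#' build_drought_schedule(50, 2, 3) # 17:19 and 33:35
#' @export
build_drought_schedule <- function(G, n_events, event_length) {
  stopifnot(length(G) == 1, length(n_events) == 1, length(event_length) == 1)
  G <- as.integer(G); n_events <- as.integer(n_events)
  event_length <- as.integer(event_length)
  if (is.na(G) || G < 1) abort("`G` must be a positive integer.")
  if (is.na(n_events) || n_events < 1) abort("`n_events` must be >= 1.")
  if (is.na(event_length) || event_length < 1) abort("`event_length` must be >= 1.")
  if (n_events * event_length > G) {
    abort(sprintf("%d events of %d generations do not fit into G = %d.",
                  n_events, event_length, G))
  }
  starts <- round(seq_len(n_events) * G / (n_events + 1))
  blocks <- lapply(starts, function(s) seq.int(s, s + event_length - 1L))
  gens <- unlist(blocks)
  if (any(gens < 1L) || any(gens > G)) {
    abort("Drought events fall outside 1..G under the regular-interval rule; supply an explicit schedule instead.")
  }
  if (anyDuplicated(gens)) {
    abort("Drought events overlap under the regular-interval rule for this G; supply an explicit schedule instead.")
  }
  structure(as.integer(gens), class = c("drought_schedule", "integer"),
            G = G, n_events = n_events, event_length = event_length)
}

#' @export
print.drought_schedule <- function(x, ...) {
  cat(sprintf("<drought_schedule> %d event(s) x %d generation(s) in 1..%d\n",
              attr(x, "n_events"), attr(x, "event_length"), attr(x, "G")))
  print(as.integer(x))
  invisible(x)
}

# Turn a schedule (indices) into the logical drought mask of length G used by
# the simulation engine. Plain integer vectors are accepted as explicit
# schedules; an empty schedule means no drought at all.
drought_mask <- function(schedule, G) {
  idx <- as.integer(schedule)
  if (length(idx) && (any(idx < 1L) || any(idx > G))) {
    abort("Schedule contains generation indices outside 1..G.")
  }
  mask <- logical(G)
  mask[idx] <- TRUE
  mask
}
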