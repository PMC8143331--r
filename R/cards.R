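#' The four cWCST key cards
#'
#' The computerized Wisconsin Card Sorting Test presents four fixed key
#' cards: one red triangle, two green stars, three yellow crosses, and four
#' blue circles, at response positions 1 to 4. All four numbers, colors and
#' shapes are pairwise distinct, so every attribute of a stimulus card
#' identifies exactly one key card on that dimension.
#'
#' @return A data frame with columns `position`, `number`, `color`, `shape`.
#' @examples
#' key_cards()
#' @export
key_cards <- function() {
  data.frame(
    position = 1:4,
    number = 1:4,
    color = .colors,
    shape = .shapes,
    stringsAsFactors = FALSE
  )
}

#' Construct and validate a stimulus card
#'
#' A valid cWCST stimulus card matches exactly one key card on each of the
#' three dimensions (number, color, shape), and the three matched key-card
#' positions are pairwise distinct. Consequently each of the three sorting
#' categories maps to a distinct response key, and exactly one key card
#' matches the stimulus on no dimension (the "no-match" key). There are 24
#' such cards; see [stimulus_deck()].
#'
#' @param number Count of depicted objects, integer in 1..4.
#' @param color One of `"red"`, `"green"`, `"yellow"`, `"blue"`.
#' @param shape One of `"triangle"`, `"star"`, `"cross"`, `"circle"`.
#' @return A list of class `"wcst_stimulus"` with elements `number`, `color`,
#'   `shape`.
#' @examples
#' stimulus_card(1, "green", "cross")
#' @export
stimulus_card <- function(number, color, shape) {
  number <- as.integer(number)
  if (!number %in% 1:4) stop("'number' must be in 1..4")
  color <- match.arg(color, .colors)
  shape <- match.arg(shape, .shapes)
  card <- structure(list(number = number, color = color, shape = shape),
                    class = "wcst_stimulus")
  pos <- match_positions(card)
  if (anyDuplicated(pos))
    stop("invalid stimulus card: attribute positions ", paste(pos, collapse = ","),
         " are not pairwise distinct (card ambiguous or equal to a key card)")
  card
}

#' @export
print.wcst_stimulus <- function(x, ...) {
  cat(sprintf("cWCST stimulus card: %d %s %s(s)\n", x$number, x$color, x$shape))
  invisible(x)
}

#' Key-card positions matched by a stimulus card
#'
#' @param stimulus A `"wcst_stimulus"` or a list with `number`, `color`,
#'   `shape`.
#' @return Named integer vector with the key-card position matched on the
#'   `color`, `shape` and `number` dimension.
#' @export
match_positions <- function(stimulus) {
  c(color = match(stimulus$color, .colors),
    shape = match(stimulus$shape, .shapes),
    number = as.integer(stimulus$number))
}

#' All valid stimulus cards
#'
#' Enumerates the 24 stimulus cards whose number, color and shape match
#' three pairwise distinct key-card positions.
#'
#' @return Data frame with columns `number`, `color`, `shape`.
#' @export
stimulus_deck <- function() {
  g <- expand.grid(number = 1:4, color_pos = 1:4, shape_pos = 1:4)
  ok <- g$number != g$color_pos & g$number != g$shape_pos &
    g$color_pos != g$shape_pos
  g <- g[ok, ]
  out <- data.frame(
    number = g$number,
    color = .colors[g$color_pos],
    shape = .shapes[g$shape_pos],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Draw a random stimulus card
#'
#' Samples uniformly from the valid card deck, excluding the card shown on
#' the previous trial (successive stimuli always differ on at least one
#' dimension). Uses the current R random number stream.
#'
#' @param previous The previous trial's stimulus (a `"wcst_stimulus"` or
#'   `NULL` for the first trial).
#' @return A `"wcst_stimulus"`.
#' @export
generate_stimulus <- function(previous = NULL) {
  deck <- stimulus_deck()
  if (!is.null(previous)) {
    same <- deck$number == previous$number & deck$color == previous$color &
      deck$shape == previous$shape
    deck <- deck[!same, ]
  }
  i <- sample.int(nrow(deck), 1L)
  stimulus_card(deck$number[i], deck$color[i], deck$shape[i])
}

#' Evaluate a card sort
#'
#' Determines which sorting category a response key-press expresses for a
#' given stimulus card, and whether the feedback is positive. The applied
#' category is the unique dimension on which the chosen key card matches the
#' stimulus; pressing the key card matching on no dimension yields
#' `"other"`. Feedback is positive if and only if the applied category
#' equals the prevailing category.
#'
#' @param stimulus A `"wcst_stimulus"` (validated on entry).
#' @param response Key position, integer in 1..4.
#' @param prevailing The prevailing category: `"color"`, `"shape"` or
#'   `"number"`.
#' @return List with `applied_category` and `feedback`
#'   (`"positive"`/`"negative"`).
#' @examples
#' st <- stimulus_card(1, "green", "cross")
#' evaluate_response(st, 3, "shape")   # applied shape, positive
#' evaluate_response(st, 3, "color")   # applied shape, negative
#' @export
evaluate_response <- function(stimulus, response, prevailing) {
  stimulus <- stimulus_card(stimulus$number, stimulus$color, stimulus$shape)
  response <- as.integer(response)
  if (!response %in% 1:4) stop("'response' must be in 1..4")
  prevailing <- match.arg(prevailing, .categories)
  pos <- match_positions(stimulus)
  hit <- names(pos)[pos == response]
  applied <- if (length(hit) == 0L) "other" else hit
  list(applied_category = applied,
       feedback = if (applied == prevailing) "positive" else "negative")
}
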