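# DASS-21 scoring: three 7-item subscales (depression, anxiety, stress),
# each a raw sum of 0-3 item ratings, range 0-21 (no DASS-42 doubling).

#' DASS-21 item-to-subscale assignment
#'
#' The standard DASS-21 key: items 3, 5, 10, 13, 16, 17, 21 load on
#' depression; 2, 4, 7, 9, 15, 19, 20 on anxiety; 1, 6, 8, 11, 12, 14, 18
#' on stress.
#'
#' @return A data.frame with columns `item` (1-21) and `scale`.
#' @export
dass_items <- function() {
  data.frame(
    item = 1:21,
    scale = c("stress", "anxiety", "depression", "anxiety", "depression",
              "stress", "anxiety", "stress", "anxiety", "depression",
              "stress", "stress", "depression", "stress", "anxiety",
              "depression", "depression", "stress", "anxiety", "anxiety",
              "depression"),
    stringsAsFactors = FALSE
  )
}

# severity cut-offs (closed integer ranges on the 0-21 subscale scores)
dass_cutoffs <- list(
  depression = c(normal = 0, mild = 5, moderate = 7, severe = 11,
                 `extremely severe` = 14),
  anxiety    = c(normal = 0, mild = 4, moderate = 6, severe = 8,
                 `extremely severe` = 10),
  stress     = c(normal = 0, mild = 8, moderate = 10, severe = 13,
                 `extremely severe` = 17)
)

#' Score a DASS-21 response into subscale scores
#'
#' Each subscale score is the raw sum of its seven item ratings (0-3), so
#' scores range 0-21. A missing item leaves that subscale undefined rather
#' than silently under-counting.
#'
#' @param items numeric vector of 21 item ratings in `{0,1,2,3}` (NA for a
#'   missing item), ordered by item number, or a named vector/list keyed
#'   `item_1` ... `item_21`.
#' @return A list with integer `depression`, `anxiety`, `stress` (NA with a
#'   `reason` attribute when any contributing item is missing) and a
#'   `categories` list from [categorize_dass()].
#' @examples
#' score_dass(rep(3, 21))  # all subscales at the 21-point maximum
#' @export
score_dass <- function(items) {
  if (!is.null(names(items))) {
    want <- paste0("item_", 1:21)
    if (all(want %in% names(items))) items <- unlist(items[want])
  }
  items <- as.numeric(items)
  if (length(items) != 21L) {
    stop("a DASS-21 response must have exactly 21 items, got ", length(items))
  }
  ok <- is.na(items) | (items %in% 0:3)
  if (!all(ok)) stop("item ratings must be integers in 0..3 or NA")
  key <- dass_items()
  out <- lapply(c("depression", "anxiety", "stress"), function(sc) {
    vals <- items[key$item[key$scale == sc]]
    if (anyNA(vals)) undefined_value("missing_item") else as.integer(sum(vals))
  })
  names(out) <- c("depression", "anxiety", "stress")
  out$categories <- lapply(names(dass_cutoffs), function(sc) {
    s <- out[[sc]]
    if (is.na(s)) NA_character_ else categorize_dass(s, sc)
  })
  names(out$categories) <- names(dass_cutoffs)
  out
}

#' Map a DASS-21 subscale score to a severity category
#'
#' Standard cut-offs. Depression: normal 0-4, mild 5-6, moderate 7-10,
#' severe 11-13, extremely severe 14+. Anxiety: normal 0-3, mild 4-5,
#' moderate 6-7, severe 8-9, extremely severe 10+. Stress: normal 0-7,
#' mild 8-9, moderate 10-12, severe 13-16, extremely severe 17+.
#'
#' @param score integer subscale score(s) in `[0, 21]`.
#' @param scale one of `"depression"`, `"anxiety"`, `"stress"`.
#' @return Character vector of severity categories (ordered factor levels
#'   `normal < mild < moderate < severe < extremely severe`).
#' @export
categorize_dass <- function(score, scale = c("depression", "anxiety", "stress")) {
  scale <- match.arg(scale)
  score <- as.numeric(score)
  if (any(!is.na(score) & (score < 0 | score > 21 | score != round(score)))) {
    stop("subscale scores must be integers in [0, 21]")
  }
  lo <- dass_cutoffs[[scale]]
  idx <- findInterval(score, lo)
  names(lo)[idx]
}

#' Severity category levels, in order
#' @return Character vector of the five severity labels, mildest first.
#' @export
dass_severity_levels <- function() {
  c("normal", "mild", "moderate", "severe", "extremely severe")
}

#' Score a table of DASS-21 item responses
#'
#' @param df data.frame with columns `participant`, `assessment_point`
#'   (e.g. `"T0"`, `"T1"`, `"T2"`) and `item_1` ... `item_21`.
#' @return A data.frame with one row per response: participant,
#'   assessment_point, the three subscale scores and their categories.
#' @export
score_dass_table <- function(df) {
  stopifnot(all(c("participant", "assessment_point") %in% names(df)),
            all(paste0("item_", 1:21) %in% names(df)))
  items <- as.matrix(df[paste0("item_", 1:21)])
  res <- lapply(seq_len(nrow(df)), function(i) score_dass(items[i, ]))
  data.frame(
    participant = df$participant,
    assessment_point = df$assessment_point,
    depression = vapply(res, function(r) as.numeric(r$depression), 0),
    anxiety = vapply(res, function(r) as.numeric(r$anxiety), 0),
    stress = vapply(res, function(r) as.numeric(r$stress), 0),
    depression_category = vapply(res, function(r) r$categories$depression %||% NA_character_, ""),
    anxiety_category = vapply(res, function(r) r$categories$anxiety %||% NA_character_, ""),
    stress_category = vapply(res, function(r) r$categories$stress %||% NA_character_, ""),
    stringsAsFactors = FALSE
  )
}
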