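# taxonomy: clinical (6-way) and conceptual (4-way) category labels.

#' Attach category labels to actions
#'
#' Joins each action's `action_code` against an action-category map,
#' attaching the 6-way clinical category and the 4-way conceptual category
#' it projects onto. Categorization is a pure function of
#' `(action_code, map)`.
#'
#' @param actions Tibble with an `action_code` column.
#' @param map Action map from [read_action_map()] (columns `action_code`,
#'   `clinical_category`, `conceptual_category`).
#' @param unmapped `"error"` (default): an action code absent from the map
#'   aborts, naming the code. `"bucket"`: unmapped codes are assigned the
#'   `uncategorized` clinical and conceptual category and reported
#'   separately in downstream tables.
#' @return The input with `clinical_category` and `conceptual_category`
#'   columns appended.
#' @export
categorize_actions <- function(actions, map,
                               unmapped = c("error", "bucket")) {
  unmapped <- match.arg(unmapped)
  require_columns(actions, "action_code", "actions")
  require_columns(map, c("action_code", "clinical_category",
                         "conceptual_category"), "map")
  actions <- as_tibble(actions)
  i <- match(actions$action_code, map$action_code)
  miss <- is.na(i)
  if (any(miss) && unmapped == "error") {
    codes <- unique(actions$action_code[miss])
    stop_input("unmapped action code(s): %s",
               paste(head(codes, 5L), collapse = ", "))
  }
  actions$clinical_category <- map$clinical_category[i]
  actions$conceptual_category <- map$conceptual_category[i]
  if (any(miss)) {
    actions$clinical_category[miss] <- "uncategorized"
    actions$conceptual_category[miss] <- "uncategorized"
  }
  actions
}

#' Action-vocabulary composition by clinical category
#'
#' Tabulates how many distinct action codes fall in each clinical category
#' and each category's share of the vocabulary, as percentages of all codes
#' rounded to one decimal (so the column sums to 100 within rounding).
#'
#' @param map Action map from [read_action_map()].
#' @return A tibble with `clinical_category`, `n_codes`, `pct_codes`.
#' @export
#' @examples
#' map <- default_action_map()
#' vocabulary_composition(map) # 161 review codes of 290 -> 55.5%
vocabulary_composition <- function(map) {
  require_columns(map, c("action_code", "clinical_category"), "map")
  if (nrow(map) == 0L) stop_input("action map is empty")
  total <- n_distinct(map$action_code)
  map |>
    distinct(.data$action_code, .data$clinical_category) |>
    count(.data$clinical_category, name = "n_codes") |>
    mutate(clinical_category = factor(
      .data$clinical_category,
      levels = union(CLINICAL_CATEGORIES,
                     unique(.data$clinical_category)))) |>
    arrange(.data$clinical_category) |>
    mutate(clinical_category = as.character(.data$clinical_category),
           pct_codes = round(100 * .data$n_codes / total, 1))
}
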