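#' Preprocess a unit-level table
#'
#' Continuous columns are median-imputed and robust-scaled (subtract the
#' median, divide by the IQR; an IQR of 0 falls back to a scale of 1 with a
#' warning).  Categorical columns are mode-imputed and integer-encoded in
#' first-seen order, with the mapping persisted so new batches are encoded
#' identically.
#'
#' @param table a data frame.
#' @param schema named character vector mapping column names to
#'   `"continuous"` or `"categorical"`; columns absent from the schema are
#'   passed through untouched.  When NULL the schema is inferred: columns
#'   with at most `max_levels` distinct non-missing values are categorical.
#' @param recipe a recipe returned by a previous call (attribute
#'   `"recipe"`), to apply identical statistics/mappings to a new batch.
#' @param max_levels inference cutoff for categorical columns (default 10).
#' @return the processed tibble, with the fitted recipe in
#'   `attr(, "recipe")`.
#' @export
preprocess <- function(table, schema = NULL, recipe = NULL, max_levels = 10) {
  table <- tibble::as_tibble(table)
  if (is.null(recipe)) {
    if (is.null(schema)) {
      schema <- vapply(table, function(col) {
        if (!is.numeric(col) ||
            length(unique(col[!is.na(col)])) <= max_levels) "categorical"
        else "continuous"
      }, character(1))
    }
    recipe <- list(schema = schema, stats = list())
    for (nm in names(schema)) {
      col <- table[[nm]]
      if (schema[[nm]] == "continuous") {
        med <- median(col, na.rm = TRUE)
        assert_that(is.finite(med), paste0("column `", nm, "` is all-missing"))
        iqr <- stats::IQR(col, na.rm = TRUE)
        if (iqr == 0) {
          warn(paste0("column `", nm, "` has zero IQR: scaling by 1"))
          iqr <- 1
        }
        recipe$stats[[nm]] <- list(center = med, scale = iqr)
      } else {
        vals <- col[!is.na(col)]
        assert_that(length(vals) > 0, paste0("column `", nm, "` is all-missing"))
        tab <- table(factor(vals, levels = unique(vals)))
        mode_val <- names(tab)[which.max(tab)]
        levels_seen <- as.character(unique(vals))
        recipe$stats[[nm]] <- list(mode = mode_val, levels = levels_seen)
      }
    }
  }
  for (nm in names(recipe$schema)) {
    if (!nm %in% names(table)) next
    st <- recipe$stats[[nm]]
    col <- table[[nm]]
    if (recipe$schema[[nm]] == "continuous") {
      col[is.na(col)] <- st$center
      table[[nm]] <- (col - st$center) / st$scale
    } else {
      col <- as.character(col)
      col[is.na(col)] <- st$mode
      code <- match(col, st$levels) - 1L
      code[is.na(code)] <- length(st$levels)  # unseen level -> new code
      table[[nm]] <- code
    }
  }
  attr(table, "recipe") <- recipe
  table
}
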