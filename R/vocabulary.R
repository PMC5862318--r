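#' Generate a drug-indicator vocabulary
#'
#' Builds the hierarchy of binary drug-utilization variables used throughout
#' the package: therapeutic *classes* nested in therapeutic *groups*, plus
#' generic-status indicators (e.g. single-source brand, multi-source generic,
#' over-the-counter) and maintenance-category indicators (chronic / acute /
#' both). Two classes are flagged as *forced*: stand-ins for the HIV
#' antiretroviral and multiple-sclerosis biological-response-modifier classes,
#' which the variable screener must always retain because of the very high
#' cost of those therapies.
#'
#' The default sizes mirror the structure of a large commercial claims
#' cohort: 239 therapeutic classes aggregating into 31 groups, 8 generic
#' indicators and 5 maintenance indicators. Classes are assigned to groups in
#' contiguous blocks whose sizes differ by at most one (every group gets at
#' least two classes so that no group duplicates a single class), and generic
#' / maintenance categories are assigned round-robin. The construction is
#' deterministic: the same sizes always give the same vocabulary.
#'
#' @param n_classes Number of therapeutic-class indicators (>= 2).
#' @param n_groups Number of therapeutic groups (>= 1, <= `n_classes / 2`).
#' @param n_generic Number of generic-status indicators.
#' @param n_maintenance Number of maintenance-category indicators.
#' @param forced Character vector of class ids to force through the variable
#'   screener, or `NULL` for the default two (HIV antivirals and MS
#'   biological response modifiers, placed at fixed positions).
#'
#' @return An object of class `drug_vocabulary`: a list with
#'   * `classes` — tibble with `class_id`, `group_id`, `generic_id`,
#'     `maintenance_id`, `label`;
#'   * `group_ids`, `generic_ids`, `maintenance_ids` — identifier vectors;
#'   * `forced_ids` — the always-retained class ids.
#' @examples
#' vocab <- generate_vocabulary()
#' nrow(vocab$classes)  # 239
#' length(vocab$group_ids)  # 31
#' @export
generate_vocabulary <- function(n_classes = 239, n_groups = 31,
                                n_generic = 8, n_maintenance = 5,
                                forced = NULL) {
  n_classes <- assert_scalar_count(n_classes, "n_classes", min = 2L)
  n_groups <- assert_scalar_count(n_groups, "n_groups", min = 1L)
  n_generic <- assert_scalar_count(n_generic, "n_generic", min = 1L)
  n_maintenance <- assert_scalar_count(n_maintenance, "n_maintenance", min = 1L)
  if (n_groups * 2L > n_classes) {
    abort("Each group needs at least two classes: require `n_classes >= 2 * n_groups`.")
  }

  class_id <- sprintf("cls_%03d", seq_len(n_classes))
  group_ids <- sprintf("grp_%02d", seq_len(n_groups))
  generic_ids <- sprintf("gen_%d", seq_len(n_generic))
  maintenance_ids <- sprintf("mnt_%d", seq_len(n_maintenance))

  # Contiguous near-equal blocks of classes per group.
  base <- n_classes %/% n_groups
  extra <- n_classes %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  group_of <- rep(group_ids, times = sizes)

  classes <- tibble(
    class_id = class_id,
    group_id = group_of,
    generic_id = generic_ids[(seq_len(n_classes) - 1L) %% n_generic + 1L],
    maintenance_id = maintenance_ids[(seq_len(n_classes) - 1L) %% n_maintenance + 1L],
    label = sprintf("therapeutic_class_%03d", seq_len(n_classes))
  )

  if (is.null(forced)) {
    pos <- unique(pmin(n_classes, c(max(2L, floor(n_classes * 0.5)), max(3L, floor(n_classes * 0.8)))))
    forced <- class_id[pos]
    classes$label[pos[1]] <- "antivirals_incl_hiv"
    if (length(pos) > 1L) classes$label[pos[2]] <- "biological_response_modifiers_incl_ms"
  } else {
    forced <- unique(as.character(forced))
    if (!all(forced %in% class_id)) {
      abort("All `forced` ids must be class ids of the vocabulary.")
    }
  }
  if (length(forced) > n_classes) {
    abort("More forced classes requested than classes in the vocabulary.")
  }

  structure(
    list(
      classes = classes,
      group_ids = group_ids,
      generic_ids = generic_ids,
      maintenance_ids = maintenance_ids,
      forced_ids = forced
    ),
    class = "drug_vocabulary"
  )
}

#' @export
print.drug_vocabulary <- function(x, ...) {
  cat(sprintf(
    "<drug_vocabulary> %d classes in %d groups; %d generic + %d maintenance indicators\n",
    nrow(x$classes), length(x$group_ids), length(x$generic_ids),
    length(x$maintenance_ids)
  ))
  cat("forced classes:", paste(x$forced_ids, collapse = ", "), "\n")
  invisible(x)
}

# All indicator ids a cohort generated from this vocabulary carries.
vocabulary_ids <- function(vocab) {
  c(vocab$classes$class_id, vocab$group_ids, vocab$generic_ids,
    vocab$maintenance_ids)
}

#' Variable sets for the learner library
#'
#' The ensemble crosses every algorithm with three predictor sets:
#' * `full` — every therapeutic-class indicator plus the generic-status and
#'   maintenance-category indicators (group aggregates are excluded because
#'   they are exact ORs of their member classes);
#' * `groups` — the parsimonious set: therapeutic-group, generic and
#'   maintenance indicators only;
#' * `screened` — filled in per fold / per fit by [screen_variables()].
#'
#' @param vocab A `drug_vocabulary`.
#' @param columns Optional character vector of columns actually present (e.g.
#'   after [drop_empty_variables()]); sets are intersected with it.
#' @return Named list of character vectors with elements `full` and `groups`.
#' @export
variable_sets <- function(vocab, columns = NULL) {
  stopifnot(inherits(vocab, "drug_vocabulary"))
  sets <- list(
    full = c(vocab$classes$class_id, vocab$generic_ids, vocab$maintenance_ids),
    groups = c(vocab$group_ids, vocab$generic_ids, vocab$maintenance_ids)
  )
  if (!is.null(columns)) sets <- lapply(sets, intersect, y = columns)
  sets
}
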