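#' The six functional class labels
#'
#' @return Character vector of the recognized labels (plus
#'   `UNCLASSIFIED`).
#' @export
classLabels <- function() {
  c("ON_OFF_DS", "OFF_SUSTAINED", "OFF_TRANSIENT", "ON_SUSTAINED",
    "ON_TRANSIENT", "ON_SMALL_TRANSIENT", "UNCLASSIFIED")
}

#' Thresholds of the rule-based classifier
#'
#' @param nvsl_ds NVSL above which an ON-OFF cell is called
#'   direction-selective (default 0.2).
#' @param duration_sustained Response-duration cutoff separating sustained
#'   from transient cells (default 0.4).
#' @param small_width_max Size-tuning width (um) below which a transient
#'   ON cell is called small-transient (default 500).
#' @param small_best_size_max Advisory best-size bound (um) for the
#'   small-transient group (default 200); recorded but not enforced.
#' @return Named list of thresholds.
#' @export
classifierThresholds <- function(nvsl_ds = 0.2, duration_sustained = 0.4,
                                 small_width_max = 500,
                                 small_best_size_max = 200) {
  stopifnot(nvsl_ds > 0, duration_sustained > 0, duration_sustained < 1,
            small_width_max > 0, small_best_size_max > 0)
  list(nvsl_ds = nvsl_ds, duration_sustained = duration_sustained,
       small_width_max = small_width_max,
       small_best_size_max = small_best_size_max)
}

.classify_one <- function(m, th) {
  pol <- m$polarity
  if (is.null(pol) || is.na(pol)) return("UNCLASSIFIED")
  if (pol == "ON_OFF") {
    if (!is.na(m$nvsl) && m$nvsl > th$nvsl_ds) return("ON_OFF_DS")
    return("UNCLASSIFIED")  # non-DS ON-OFF cells are not one of the six groups
  }
  dur <- m$response_duration
  if (is.na(dur)) return("UNCLASSIFIED")
  if (pol == "OFF") {
    if (dur >= th$duration_sustained) return("OFF_SUSTAINED")
    return("OFF_TRANSIENT")
  }
  ## pol == "ON"
  w <- m$size_tuning_width_um
  if (dur < th$duration_sustained && !is.na(w) && w < th$small_width_max)
    return("ON_SMALL_TRANSIENT")
  if (dur >= th$duration_sustained) "ON_SUSTAINED" else "ON_TRANSIENT"
}

#' Classify cells into the six functional groups
#'
#' Decision order: (1) ON-OFF polarity with NVSL above `nvsl_ds` gives
#' `ON_OFF_DS`; (2) OFF cells split into sustained vs transient by
#' `duration_sustained`; (3) ON cells are `ON_SMALL_TRANSIENT` when
#' transient with a size-tuning width below `small_width_max`, otherwise
#' sustained/transient by duration. Unresponsive cells, cells with
#' missing prerequisites, and non-direction-selective ON-OFF cells are
#' `UNCLASSIFIED`. The classifier is total: every row gets exactly one
#' label. The advisory best-size criterion for the small-transient group
#' is recorded in `small_size_advisory` (TRUE when the measured best size
#' exceeds `small_best_size_max`), never enforced.
#'
#' @param metrics Metrics table from [computeCellMetrics()] (or any
#'   `data.frame`/list with the needed fields).
#' @param thresholds From [classifierThresholds()].
#' @return `data.frame`: `cell_id` (if present), `group` (if present),
#'   `label`, `small_size_advisory`.
#' @export
classifyCells <- function(metrics, thresholds = classifierThresholds()) {
  if (!is.data.frame(metrics)) metrics <- as.data.frame(metrics)
  labels <- vapply(seq_len(nrow(metrics)), function(i)
    .classify_one(as.list(metrics[i, ]), thresholds), "")
  advisory <- labels == "ON_SMALL_TRANSIENT" &
    !is.na(metrics$best_size_um) &
    metrics$best_size_um > thresholds$small_best_size_max
  out <- data.frame(label = labels, small_size_advisory = advisory)
  for (col in c("group", "cell_id"))
    if (col %in% names(metrics)) out <- cbind(metrics[col], out)
  out
}

#' Tabulate class counts per projection group
#'
#' @param labels `data.frame` with `group` and `label` columns (from
#'   [classifyCells()]).
#' @param groups Optional vector of allowed groups; rows with other
#'   groups raise an error.
#' @return Integer matrix, classes x groups (all of [classLabels()] as
#'   rows).
#' @export
tabulateClasses <- function(labels, groups = NULL) {
  stopifnot(all(c("group", "label") %in% names(labels)))
  if (is.null(groups)) groups <- sort(unique(labels$group))
  if (!all(labels$group %in% groups))
    stop("unknown group(s): ",
         paste(setdiff(unique(labels$group), groups), collapse = ", "))
  tab <- table(factor(labels$label, levels = classLabels()),
               factor(labels$group, levels = groups))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- c("class", "group")
  m
}

#' Build a 2x2 contingency table: class membership by projection group
#'
#' Rows are the two groups; columns are membership in `classA` versus
#' either all remaining cells (`classB = NULL`) or a second class.
#'
#' @param labels `data.frame` with `group` and `label`.
#' @param classA Class of interest.
#' @param groups The two groups to compare (default: the two present).
#' @param classB Optional second class for a class-vs-class table.
#' @return 2x2 integer matrix with informative dimnames.
#' @export
classContingency <- function(labels, classA, groups = NULL,
                             classB = NULL) {
  if (is.null(groups)) groups <- sort(unique(labels$group))
  stopifnot(length(groups) == 2)
  if (!all(labels$group %in% groups))
    stop("unknown group(s) present")
  sub <- labels[labels$group %in% groups, ]
  inA <- sub$label == classA
  other <- if (is.null(classB)) !inA else sub$label == classB
  m <- vapply(groups, function(g)
    c(sum(inA & sub$group == g), sum(other & sub$group == g)),
    integer(2))
  m <- t(m)
  colnames(m) <- c(classA, if (is.null(classB)) "other" else classB)
  names(dimnames(m)) <- c("group", "class")
  m
}
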