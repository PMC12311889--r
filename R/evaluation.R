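#' Majority-vote matching of predicted clusters to baseline classes
#'
#' For every predicted cluster, tallies the baseline classes of its pixels
#' (ignoring unlabeled `-1` baseline pixels) and maps the cluster to the
#' most frequent class, ties to the smallest class id. A cluster lying
#' entirely on unlabeled pixels stays unassigned. Several clusters may map
#' to one class — this is what merges over-segmented clusters down to the
#' baseline classes.
#'
#' @param pred predicted [LabelMap-class]
#' @param baseline baseline [LabelMap-class] (may contain `-1`)
#' @return a [MatchingTable-class]
#' @export
matchClusters <- function(pred, baseline) {
  checkSameGrid(pred, baseline)
  ## align baseline pixels to prediction order
  key <- function(m) paste(m@coords[, 1L], m@coords[, 2L])
  bl <- baseline@labels[match(key(pred), key(baseline))]
  pl <- pred@labels
  clusters <- sort(unique(pl[pl >= 0L]))
  classes <- sort(unique(bl[bl >= 0L]))
  tallies <- matrix(0L, length(clusters), length(classes),
                    dimnames = list(clusters, classes))
  mapping <- rep(NA_integer_, length(clusters))
  labeled <- bl >= 0L
  for (ci in seq_along(clusters)) {
    sel <- pl == clusters[ci] & labeled
    if (!any(sel)) next
    tab <- table(factor(bl[sel], levels = classes))
    tallies[ci, ] <- as.integer(tab)
    mapping[ci] <- classes[which.max(tab)]  # which.max: first max = smallest id
  }
  new("MatchingTable", clusters = as.integer(clusters),
      mapping = mapping, tallies = tallies)
}

#' @describeIn matchClusters the cluster-to-class map as a named integer
#'   vector (`NA` = unassigned)
#' @param table a `MatchingTable`
#' @export
clusterMapping <- function(table) {
  stats::setNames(table@mapping, table@clusters)
}

setMethod("show", "MatchingTable", function(object) {
  cat(sprintf("MatchingTable: %d predicted clusters -> %d baseline classes\n",
              length(object@clusters), ncol(object@tallies)))
  for (i in seq_along(object@clusters))
    cat(sprintf("  cluster %d -> %s  (votes: %s)\n", object@clusters[i],
                ifelse(is.na(object@mapping[i]), "unassigned",
                       object@mapping[i]),
                paste(object@tallies[i, ], collapse = "/")))
})

#' Apply a matching table to a predicted label map
#'
#' Replaces each predicted cluster id by its matched baseline class;
#' unassigned clusters become `-1`.
#'
#' @param pred predicted [LabelMap-class]
#' @param table a [MatchingTable-class] covering all predicted clusters
#' @return the relabeled [LabelMap-class]
#' @export
applyMatching <- function(pred, table) {
  pl <- pred@labels
  present <- unique(pl[pl >= 0L])
  missing <- setdiff(present, table@clusters)
  if (length(missing))
    stopf("matching table lacks predicted cluster(s): %s",
          paste(missing, collapse = ", "))
  out <- pl
  idx <- match(pl, table@clusters)
  mapped <- table@mapping[idx]
  out[pl >= 0L] <- ifelse(is.na(mapped[pl >= 0L]), -1L, mapped[pl >= 0L])
  labelMap(pred@coords, out, width = pred@width, height = pred@height,
           provenance = "prediction")
}

#' Segmentation accuracy against a baseline
#'
#' `100 * correct / labeled` over baseline-labeled pixels only: unlabeled
#' (`-1`) baseline pixels are excluded from the denominator, while matched
#' `-1` predictions on labeled baseline pixels count as incorrect.
#'
#' @param matched matched [LabelMap-class] (see [applyMatching()])
#' @param baseline baseline [LabelMap-class]
#' @return accuracy percentage in `[0, 100]`
#' @export
segmentationAccuracy <- function(matched, baseline) {
  checkSameGrid(matched, baseline)
  key <- function(m) paste(m@coords[, 1L], m@coords[, 2L])
  bl <- baseline@labels[match(key(matched), key(baseline))]
  ml <- matched@labels
  labeled <- bl >= 0L
  if (!any(labeled)) stopf("baseline has no labeled pixels")
  100 * sum(ml[labeled] == bl[labeled]) / sum(labeled)
}

#' One-call segmentation evaluation
#'
#' Convenience wrapper: match clusters, apply the matching, compute
#' accuracy.
#'
#' @param pred predicted [LabelMap-class]
#' @param baseline baseline [LabelMap-class]
#' @return list with `table`, `matched` map and `accuracy`
#' @export
evaluateSegmentation <- function(pred, baseline) {
  tab <- matchClusters(pred, baseline)
  matched <- applyMatching(pred, tab)
  list(table = tab, matched = matched,
       accuracy = segmentationAccuracy(matched, baseline))
}

#' Write an evaluation report as CSV
#'
#' One row per predicted cluster: mapped class, votes per baseline class,
#' plus an overall-accuracy attribute row appended as a comment-free
#' trailing line is avoided; the overall accuracy is returned invisibly.
#'
#' @param evalResult result of [evaluateSegmentation()]
#' @param path output file
#' @export
writeEvaluationReport <- function(evalResult, path) {
  tab <- evalResult$table
  df <- data.frame(cluster = tab@clusters,
                   mapped_class = ifelse(is.na(tab@mapping), "unassigned",
                                         tab@mapping))
  votes <- as.data.frame(tab@tallies)
  names(votes) <- paste0("votes_class_", colnames(tab@tallies))
  df <- cbind(df, votes, overall_accuracy = evalResult$accuracy)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(evalResult$accuracy)
}
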