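# Ward minimum-variance clustering of treatments on standardized
# life-table and enzyme features, with Newick export.

#' Assemble the standardized treatment-by-feature matrix
#'
#' Joins per-treatment demographic parameters and enzyme-activity means,
#' selects the requested features and z-scores each column (mean 0, sd 1).
#' Standardization matters here because the raw feature scales differ by
#' orders of magnitude (lambda is near 1 while GRR can exceed 600), and
#' unscaled Ward clustering would be dominated by the largest feature.
#'
#' @param life_table Data frame with a `treatment` column and the
#'   demographic parameter columns (`GRR`, `R0`, `r`, `lambda`, `T`).
#' @param enzymes Optional data frame with a `treatment` column and enzyme
#'   mean-activity columns (`SOD`, `POD`, `CAT`).
#' @param features Feature columns to use, in order.  Defaults to the five
#'   demographic parameters plus the three enzymes when `enzymes` is given,
#'   otherwise the demographic parameters alone.
#' @return Object of class `"feature_matrix"`: list with `values`
#'   (standardized matrix, treatments as rownames), `features` and
#'   `provenance` (named character: `"life_table"` or `"enzyme"` per
#'   feature).
#' @export
build_feature_matrix <- function(life_table, enzymes = NULL,
                                 features = NULL) {
  life_table <- as.data.frame(life_table)
  if (!"treatment" %in% names(life_table)) {
    stop("life_table must have a 'treatment' column")
  }
  merged <- life_table
  prov <- stats::setNames(rep("life_table", ncol(life_table)),
                          names(life_table))
  if (!is.null(enzymes)) {
    enzymes <- as.data.frame(enzymes)
    if (!"treatment" %in% names(enzymes)) {
      stop("enzymes must have a 'treatment' column")
    }
    merged <- merge(life_table, enzymes, by = "treatment", sort = FALSE)
    prov <- c(prov, stats::setNames(
      rep("enzyme", ncol(enzymes) - 1), setdiff(names(enzymes), "treatment")))
  }
  if (is.null(features)) {
    features <- intersect(c("GRR", "R0", "r", "lambda", "T",
                            "SOD", "POD", "CAT"), names(merged))
  }
  missing_f <- setdiff(features, names(merged))
  if (length(missing_f) > 0) {
    stop("missing feature column(s): ", paste(missing_f, collapse = ", "))
  }
  m <- as.matrix(merged[, features, drop = FALSE])
  rownames(m) <- merged$treatment
  if (anyNA(m)) stop("feature matrix has missing cells")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature column(s): ",
         paste(features[sds == 0], collapse = ", "))
  }
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  structure(list(values = z, features = features,
                 provenance = prov[features]),
            class = "feature_matrix")
}

#' Ward minimum-variance agglomeration
#'
#' Hierarchical clustering by Ward's criterion on Euclidean distances
#' (the "ward.D2" convention: the Lance-Williams update is applied to
#' squared dissimilarities and merge heights are reported on the distance
#' scale, so `height^2 / 2` is the increase in total within-cluster sum of
#' squares at each merge).  Heights are monotone non-decreasing; Ward
#' produces no inversions.
#'
#' @param x A `"feature_matrix"` or a plain numeric matrix with rownames.
#' @return Object of class `"ward_linkage"`: list with `merge`, `height`,
#'   `labels`, `n` and the underlying `"hclust"` object.
#' @export
ward_linkage <- function(x) {
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to cluster")
  if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  structure(list(merge = hc$merge, height = hc$height, labels = hc$labels,
                 n = nrow(x), hclust = hc),
            class = "ward_linkage")
}

#' @export
print.ward_linkage <- function(x, ...) {
  cat("Ward linkage over", x$n, "leaves;",
      length(x$height), "merges, heights",
      paste(format(range(x$height), digits = 3), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
plot.ward_linkage <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}

#' Cut a linkage into k clusters
#'
#' @param linkage A `"ward_linkage"`.
#' @param k Number of clusters, 1 <= k <= n.
#' @return Named integer vector of cluster memberships.
#' @export
cut_linkage <- function(linkage, k) {
  if (k < 1 || k > linkage$n) {
    stop("k must be between 1 and the number of leaves (", linkage$n, ")")
  }
  stats::cutree(linkage$hclust, k = k)
}

#' Newick string for a linkage
#'
#' Ultrametric export: every leaf sits at depth 0 and each internal node at
#' its merge height, so a branch length is the height difference between a
#' node and its parent and root-to-leaf path lengths equal the root merge
#' height.
#'
#' @param linkage A `"ward_linkage"`.
#' @return Single-element character vector (with trailing `;`).
#' @export
as_newick <- function(linkage) {
  merge <- linkage$merge
  height <- linkage$height
  labels <- linkage$labels
  node_str <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%.10g", labels[-i], parent_h)
    } else {
      sprintf("(%s,%s):%.10g",
              node_str(merge[i, 1], height[i]),
              node_str(merge[i, 2], height[i]),
              parent_h - height[i])
    }
  }
  root <- nrow(merge)
  sprintf("(%s,%s);",
          node_str(merge[root, 1], height[root]),
          node_str(merge[root, 2], height[root]))
}

#' Cut a dendrogram and export it as Newick
#'
#' @param linkage A `"ward_linkage"`.
#' @param k Number of clusters for the cut.
#' @param path Optional file path; when given, the Newick string is written
#'   there.
#' @return List with `clusters` (named integer vector) and `newick`.
#' @export
cut_and_export <- function(linkage, k, path = NULL) {
  clusters <- cut_linkage(linkage, k)
  nwk <- as_newick(linkage)
  if (!is.null(path)) writeLines(nwk, path)
  list(clusters = clusters, newick = nwk)
}
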