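# All-vs-all comparison matrices and their CSV / plot outputs.

#' All-vs-all comparison of signatures
#'
#' Builds a labeled square matrix of pairwise scores. `"jaccard"` and
#' `"cosine"` matrices are symmetric with a unit diagonal; `"containment"`
#' (row in column) is asymmetric. By default cosine similarity is used iff
#' every signature tracks abundance and `ignore_abundance` is unset,
#' mirroring the comparison tool's behaviour; otherwise Jaccard.
#'
#' @param signatures List of >= 2 compatible `signature`s.
#' @param mode `"auto"`, `"jaccard"`, `"cosine"` or `"containment"`.
#' @param ignore_abundance Flatten sketches before comparing.
#' @param ksize K size to compare at.
#' @return A numeric matrix with signature names as dimnames (input order)
#'   and a `mode` attribute.
#' @export
compare_signatures <- function(signatures, mode = "auto",
                               ignore_abundance = FALSE, ksize = NULL) {
  stopifnot(length(signatures) >= 2)
  mode <- match.arg(mode, c("auto", "jaccard", "cosine", "containment"))
  mol <- signatures[[1]]$sketches[[1]]$molecule
  sks <- lapply(signatures, sig_sketch, ksize = ksize, molecule = mol)
  if (ignore_abundance) sks <- lapply(sks, sketch_flatten)
  if (mode == "auto") {
    mode <- if (all(vapply(sks, `[[`, TRUE, "track_abundance"))) "cosine"
            else "jaccard"
  }
  labels <- vapply(signatures, `[[`, "", "name")
  n <- length(sks)
  pairfun <- switch(mode,
    jaccard = jaccard,
    cosine = cosine_sim,
    containment = containment
  )
  M <- diag(1, n)
  dimnames(M) <- list(labels, labels)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (mode != "containment" && j < i) {
        M[i, j] <- M[j, i]
        next
      }
      M[i, j] <- tryCatch(pairfun(sks[[i]], sks[[j]]), error = function(e) {
        stop(sprintf("cannot compare '%s' with '%s': %s",
                     labels[i], labels[j], conditionMessage(e)), call. = FALSE)
      })
    }
  }
  attr(M, "mode") <- mode
  M
}

#' Write a comparison matrix as CSV
#'
#' Layout: a header row of signature labels followed by `n` data rows of
#' `n` floats, no row-label column — directly loadable with `read.csv()`
#' for downstream ordination or clustering.
#'
#' @param mat Matrix from [compare_signatures()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compare_csv <- function(mat, path) {
  df <- as.data.frame(mat)
  colnames(df) <- colnames(mat)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read back a comparison matrix CSV
#'
#' @param path CSV written by [write_compare_csv()].
#' @return A labeled numeric matrix.
#' @export
read_compare_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  m
}

#' Plot a comparison matrix
#'
#' Writes two PNG images: a hierarchically clustered heatmap
#' (`<basename>.matrix.png`) and the corresponding dendrogram
#' (`<basename>.dendro.png`). Clustering uses average linkage on
#' `1 - similarity` distances; `vmin` sets the color-scale floor so weak
#' similarities can be blanked out.
#'
#' @param mat Square labeled similarity matrix.
#' @param basename Output path prefix.
#' @param vmin Color floor in `[0, 1)`.
#' @param show_labels Draw axis labels.
#' @return Invisibly, a list with `files` (the two paths) and `leaf_order`
#'   (labels in dendrogram order).
#' @export
plot_compare <- function(mat, basename, vmin = 0, show_labels = TRUE) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop("comparison plot requires a square matrix")
  labels <- colnames(mat)
  hc <- hclust(as.dist(1 - mat), method = "average")
  ord <- hc$order
  m <- mat[ord, ord, drop = FALSE]
  m[m < vmin] <- vmin

  heat_file <- paste0(basename, ".matrix.png")
  png(heat_file, width = 800, height = 800)
  op <- par(mar = c(8, 8, 2, 2))
  image(seq_len(nrow(m)), seq_len(ncol(m)), t(m[rev(seq_len(nrow(m))), ]),
        zlim = c(vmin, 1), col = hcl.colors(64, "viridis"),
        axes = FALSE, xlab = "", ylab = "")
  if (show_labels) {
    axis(1, at = seq_len(ncol(m)), labels = labels[ord], las = 2, cex.axis = 0.8)
    axis(2, at = seq_len(nrow(m)), labels = rev(labels[ord]), las = 2,
         cex.axis = 0.8)
  }
  par(op)
  dev.off()

  dendro_file <- paste0(basename, ".dendro.png")
  png(dendro_file, width = 800, height = 500)
  plot(as.dendrogram(hc), main = "", ylab = "1 - similarity",
       leaflab = if (show_labels) "perpendicular" else "none")
  dev.off()

  invisible(list(files = c(heat_file, dendro_file),
                 leaf_order = labels[ord]))
}
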