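#' @include AllClasses.R matrix-explorer.R
NULL

.diverging_palette <- function(k = 255) {
  grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(k)
}

.cluster_palette <- function(k) {
  grDevices::hcl(h = seq(15, 375, length.out = k + 1)[seq_len(k)],
                 c = 100, l = 65)
}

# height at which cutting the dendrogram leaves k sub-trees
.cut_height <- function(h, k) {
  n <- length(h$height) + 1L
  if (k >= n) return(min(h$height) / 2)
  if (k <= 1) return(max(h$height) * 1.05)
  mean(sort(h$height, decreasing = TRUE)[c(k - 1, k)])
}

#' Render the clustered adjacency matrix as a static figure
#'
#' Heatmap of the weight matrix in dendrogram leaf order with the
#' dendrogram in the top margin, a red dotted line at the cut height,
#' and colour bars marking each sub-tree under the dendrogram. Cell
#' colours and (in [renderNetwork()]) edge colours are drawn from the
#' same diverging scale over `[-1, 1]`. Deterministic for fixed input.
#'
#' @param cm a [ClusteredMatrix-class]
#' @param path output PNG path
#' @param cut_line draw the dotted cut-height line (default `TRUE`)
#' @param width,height device size in pixels
#' @return the path, invisibly
#' @export
renderMatrix <- function(cm, path, cut_line = TRUE,
                         width = 800, height = 900) {
  if (nrow(cm@graph@nodes) > 500)
    warning("more than 500 nodes: the matrix view is designed for up to 500")
  w <- weightMatrix(cm@graph)
  ord <- cm@order
  wv <- w[ord, ord]
  n <- nrow(wv)
  pal <- .diverging_palette()
  kcol <- .cluster_palette(length(unique(cm@assignment)))
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(c(1, 2, 3), ncol = 1), heights = c(2.2, 0.25, 6))
  graphics::par(mar = c(0, 4, 2, 2))
  graphics::plot(stats::as.dendrogram(cm@hclust), leaflab = "none",
                 yaxs = "i")
  if (cut_line)
    graphics::abline(h = .cut_height(cm@hclust, cm@cut_level),
                     col = "red", lty = 3, lwd = 2)
  graphics::par(mar = c(0.2, 4, 0.2, 2))
  graphics::image(seq_len(n), 1, matrix(cm@assignment[ord], ncol = 1),
                  col = kcol[sort(unique(cm@assignment))], axes = FALSE,
                  xlab = "", ylab = "")
  graphics::par(mar = c(5, 4, 0.5, 2))
  graphics::image(seq_len(n), seq_len(n), wv[, n:1, drop = FALSE],
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "")
  labs <- cm@graph@nodes$label[ord]
  graphics::axis(1, at = seq_len(n), labels = labs, las = 2, cex.axis = 0.6,
                 tick = FALSE)
  graphics::axis(2, at = n:1, labels = labs, las = 2, cex.axis = 0.6,
                 tick = FALSE)
  invisible(path)
}

#' Render a node-link diagram as a static figure
#'
#' Force-directed layout (deterministic for a fixed seed), nodes
#' coloured by a metadata key (`colour_group` from [colorNodes()], an
#' annotation status, any column), all node labels drawn, edge colour
#' from the same diverging weight scale as the matrix cells.
#'
#' @param graph an [InteractionGraph-class]
#' @param path output PNG path
#' @param colour_key node metadata column for colouring (`NULL`: single
#'   colour)
#' @param seed layout seed
#' @param width,height device size in pixels
#' @return the path, invisibly
#' @export
renderNetwork <- function(graph, path, colour_key = NULL, seed = 1,
                          width = 800, height = 800) {
  if (nrow(graph@nodes) > 500)
    warning("more than 500 nodes: the node-link view is designed for up to 500")
  pal <- .diverging_palette()
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 1, 1))
  if (nrow(graph@nodes) == 0) {
    graphics::plot.new()
    return(invisible(path))
  }
  xy <- layoutGraph(graph, dims = 2, seed = seed)
  grp <- if (!is.null(colour_key) && colour_key %in% names(graph@nodes)) {
    g <- as.character(graph@nodes[[colour_key]])
    g[is.na(g)] <- "unknown"
    g
  } else rep("all", nrow(graph@nodes))
  lev <- sort(unique(grp))
  ncol <- stats::setNames(.cluster_palette(length(lev)), lev)
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "")
  lk <- graph@links
  if (nrow(lk)) {
    ci <- pmax(1L, pmin(255L, as.integer(round((lk$weight + 1) / 2 * 254 + 1))))
    graphics::segments(xy[lk$source, 1], xy[lk$source, 2],
                       xy[lk$target, 1], xy[lk$target, 2],
                       col = pal[ci], lwd = 1.5)
  }
  graphics::points(xy, pch = 21, bg = ncol[grp], cex = 2)
  graphics::text(xy, labels = graph@nodes$label, pos = 3, cex = 0.7)
  if (length(lev) > 1)
    graphics::legend("topleft", legend = lev, pt.bg = ncol, pch = 21,
                     bty = "n", cex = 0.8)
  invisible(path)
}
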