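#' Visual theme constants
#'
#' Central color table used by the pre-defined layouts: duplication nodes are
#' blue, speciation nodes red, inferred gene losses dashed grey; positive
#' silhouettes green, negative red; heatmap ramp from blue (low) through
#' white to red (high).
#'
#' @return A named list of color strings.
#' @export
treescope_theme <- function() list(
  duplication = "#0000ff",
  speciation = "#ff0000",
  loss = "#808080",
  silhouette_positive = "#00a000",
  silhouette_negative = "#d00000",
  edge = "#000000",
  text = "#000000",
  heat_low = "#0000ff",
  heat_mid = "#ffffff",
  heat_high = "#ff0000"
)

.valid_color <- function(x) {
  is.character(x) && length(x) == 1L &&
    (grepl("^#[0-9a-fA-F]{6}([0-9a-fA-F]{2})?$", x) ||
       x %in% grDevices::colors())
}

#' Per-node visual style
#'
#' @param shape Node marker: `"circle"`, `"square"` or `"none"`.
#' @param size Marker size in px (>= 0).
#' @param fill_color,line_color Hex (`"#rrggbb"`) or named colors.
#' @param line_style `"solid"` or `"dashed"` branch lines.
#' @param visible Draw this node (marker and leaf label) at all?
#' @return An object of class `node_style`.
#' @export
node_style <- function(shape = c("none", "circle", "square"), size = 0,
                       fill_color = "#000000", line_style = c("solid", "dashed"),
                       line_color = "#000000", visible = TRUE) {
  shape <- match.arg(shape)
  line_style <- match.arg(line_style)
  if (!is.numeric(size) || length(size) != 1L || size < 0)
    stop("size must be a single number >= 0")
  if (!.valid_color(fill_color)) stop("invalid fill_color: ", fill_color)
  if (!.valid_color(line_color)) stop("invalid line_color: ", line_color)
  structure(list(shape = shape, size = size, fill_color = fill_color,
                 line_style = line_style, line_color = line_color,
                 visible = isTRUE(visible)),
            class = "node_style")
}

new_face <- function(kind, payload, position) {
  position <- match.arg(position, c("branch_right", "aligned_right",
                                    "branch_top"))
  structure(list(kind = kind, payload = payload, position = position),
            class = "face")
}

#' Faces: graphical items attached to nodes
#'
#' A face is an extra visual element drawn next to a node: a text label, a
#' strip of aligned sequence residues, a bar graph or heatmap row of numeric
#' values, or an external image. Faces are positioned at `"branch_right"`
#' (right of the node), `"aligned_right"` (in a column block right of the
#' deepest leaf, where alignments and heatmaps line up) or `"branch_top"`.
#'
#' @param text,sequence Character payloads (non-empty).
#' @param values Finite numeric payload.
#' @param href Image reference for [image_face()].
#' @param position See above.
#' @return An object of class `face`.
#' @name faces
NULL

#' @rdname faces
#' @export
text_face <- function(text, position = "branch_right") {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("text face needs a non-empty string")
  new_face("text", text, position)
}

#' @rdname faces
#' @export
sequence_face <- function(sequence, position = "aligned_right") {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence face needs a non-empty string")
  new_face("sequence_strip", sequence, position)
}

#' @rdname faces
#' @export
bar_face <- function(values, position = "branch_right") {
  if (!is.numeric(values) || !length(values) || any(!is.finite(values)))
    stop("bar face needs finite numeric values")
  new_face("bar_graph", values, position)
}

#' @rdname faces
#' @export
heatmap_face <- function(values, position = "aligned_right") {
  if (!is.numeric(values) || !length(values))
    stop("heatmap face needs numeric values")
  new_face("heatmap_row", values, position)
}

#' @rdname faces
#' @export
image_face <- function(href, position = "branch_right") {
  if (!is.character(href) || length(href) != 1L || !nzchar(href))
    stop("image face needs a reference string")
  new_face("external_image", href, position)
}

# layout helpers -------------------------------------------------------------

basic_layout <- function(node) list(style = node_style(), faces = list())

#' Pre-defined layout for phylogenetic trees with inferred events
#'
#' Duplication nodes are drawn as blue circles and speciation nodes as red
#' circles (`"event"` feature); loss leaves (`evoltype = "L"`) get dashed
#' grey branches; leaves carrying a linked sequence get an aligned
#' sequence-strip face. Unannotated nodes keep a neutral style.
#'
#' @param node A `tree_node`.
#' @return `list(style =, faces =)` as consumed by [render_svg()].
#' @export
phylo_layout <- function(node) {
  th <- treescope_theme()
  style <- node_style()
  faces <- list()
  ev <- node$features[["event"]]
  if (identical(ev, "duplication"))
    style <- node_style(shape = "circle", size = 6, fill_color = th$duplication)
  else if (identical(ev, "speciation"))
    style <- node_style(shape = "circle", size = 6, fill_color = th$speciation)
  if (identical(node$features[["evoltype"]], "L"))
    style <- node_style(line_style = "dashed", line_color = th$loss)
  seq <- node$features[["sequence"]]
  if (is_leaf(node) && !is.null(seq))
    faces <- c(faces, list(sequence_face(seq)))
  list(style = style, faces = faces)
}

#' Pre-defined layout for clustering trees
#'
#' Leaves show their linked profile as a heatmap row; internal nodes with a
#' computed `"silhouette"` feature get a bubble whose size is proportional to
#' the absolute silhouette — green for positive values, red for negative,
#' hidden at exactly 0. Internal nodes may additionally show a bar graph of
#' their mean profile via `render_svg(..., layout = cluster_layout)` after
#' [validate_clusters()].
#'
#' @param node A `tree_node`.
#' @param bubble_scale Bubble radius in px for |silhouette| = 1.
#' @return `list(style =, faces =)` as consumed by [render_svg()].
#' @export
cluster_layout <- function(node, bubble_scale = 12) {
  th <- treescope_theme()
  style <- node_style()
  faces <- list()
  if (is_leaf(node)) {
    p <- node$features[["profile"]]
    if (!is.null(p) && any(!is.na(p)))
      faces <- c(faces, list(heatmap_face(p)))
  } else {
    s <- node$features[["silhouette"]]
    if (!is.null(s)) {
      if (s == 0) {
        style <- node_style(shape = "circle", size = 0, visible = FALSE)
      } else {
        col <- if (s > 0) th$silhouette_positive else th$silhouette_negative
        style <- node_style(shape = "circle", size = bubble_scale * abs(s),
                            fill_color = col)
      }
    }
  }
  list(style = style, faces = faces)
}

# SVG rendering ---------------------------------------------------------------

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

num <- function(x) sprintf("%.2f", x)

heat_color <- function(v, lo, hi) {
  th <- treescope_theme()
  if (is.na(v)) return("#cccccc")
  t <- if (hi > lo) (v - lo) / (hi - lo) else 0.5
  ramp <- function(c1, c2, f) {
    a <- grDevices::col2rgb(c1)[, 1L]
    b <- grDevices::col2rgb(c2)[, 1L]
    grDevices::rgb(t(a + (b - a) * f), maxColorValue = 255)
  }
  if (t <= 0.5) ramp(th$heat_low, th$heat_mid, t * 2)
  else ramp(th$heat_mid, th$heat_high, (t - 0.5) * 2)
}

#' Render a tree as a standalone SVG document
#'
#' Rule-driven static rendering: for every node the `layout` function returns
#' a [node_style()] and a list of faces, which control branch style, node
#' markers and attached graphics. Leaves are placed top to bottom in
#' traversal order; each node's horizontal position is its root-path length
#' times `scale` (or its depth when `ultrametric`, with all leaves
#' right-aligned — the usual display for clustering dendrograms). Output is
#' deterministic for fixed inputs, and rendering never mutates the tree.
#'
#' @param root A `tree_node`.
#' @param layout A function `node -> list(style, faces)`; default: neutral
#'   style, no faces.
#' @param width Target branch-area width in px (branch lengths are scaled to
#'   fit unless `scale` is given).
#' @param scale Branch-length-to-px factor; `NULL` fits to `width`.
#' @param ultrametric Right-align leaves (equal depth display)?
#' @param row_height Vertical spacing between leaves in px.
#' @return The SVG document as a character scalar.
#' @examples
#' svg <- render_svg(parse_newick("((A,B),C);"))
#' @export
render_svg <- function(root, layout = NULL, width = 600, scale = NULL,
                       ultrametric = FALSE, row_height = 20) {
  if (is.null(layout)) layout <- basic_layout
  nodes <- traverse(root, "preorder")
  lay <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    res <- tryCatch(layout(nd), error = function(e) {
      stop("layout function failed on node '", nd$name, "' (id ", nd$id,
           "): ", conditionMessage(e))
    })
    if (!is.list(res) || !inherits(res$style, "node_style"))
      stop("layout must return list(style = node_style(), faces = list())",
           " for node '", nd$name, "'")
    lay[[i]] <- res
  }
  idx <- integer(0)
  idx[as.character(vapply(nodes, function(x) x$id, integer(1L)))] <-
    seq_along(nodes)
  pos_of <- function(nd) idx[[as.character(nd$id)]]

  # x: cumulative path length from root; y: leaves in order, internals at the
  # mean of their children
  xdepth <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    xdepth[i] <- if (is.null(nd$parent) || i == 1L) 0
                 else xdepth[pos_of(nd$parent)] + nd$dist
  }
  maxd <- max(xdepth, 1e-9)
  if (is.null(scale)) scale <- width / maxd
  margin <- 10
  ys <- numeric(length(nodes))
  leaf_i <- 0L
  for (nd in traverse(root, "postorder")) {
    i <- pos_of(nd)
    if (is_leaf(nd)) {
      leaf_i <- leaf_i + 1L
      ys[i] <- margin + (leaf_i - 0.5) * row_height
    } else {
      cy <- vapply(nd$children, function(c) ys[pos_of(c)], numeric(1L))
      ys[i] <- mean(range(cy))
    }
  }
  xs <- margin + xdepth * scale
  if (ultrametric) {
    # leaves right-aligned; internals keep their branch-proportional depth
    for (i in seq_along(nodes)) if (is_leaf(nodes[[i]]))
      xs[i] <- margin + maxd * scale
  }
  x_align <- max(xs) + 8 +
    max(c(0, vapply(nodes, function(nd)
      if (is_leaf(nd)) 7 * nchar(nd$name) else 0, numeric(1L))))

  th <- treescope_theme()
  el <- character(0)
  add <- function(...) el[[length(el) + 1L]] <<- paste0(...)
  heat_vals <- unlist(lapply(lay, function(l)
    unlist(lapply(l$faces, function(f)
      if (f$kind == "heatmap_row") f$payload))), use.names = FALSE)
  hlo <- if (length(heat_vals)) min(heat_vals, na.rm = TRUE) else 0
  hhi <- if (length(heat_vals)) max(heat_vals, na.rm = TRUE) else 1

  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    st <- lay[[i]]$style
    if (!st$visible) next
    # branch: vertical connector at the parent's x, then horizontal to node
    if (!is.null(nd$parent) && !is.na(idx[as.character(nd$parent$id)])) {
      p <- pos_of(nd$parent)
      dash <- if (st$line_style == "dashed") ' stroke-dasharray="4,3"' else ""
      add('<path d="M', num(xs[p]), " ", num(ys[p]),
          " V", num(ys[i]), " H", num(xs[i]),
          '" fill="none" stroke="', st$line_color, '"', dash, "/>")
    }
    if (st$shape != "none" && st$size > 0) {
      if (st$shape == "circle")
        add('<circle cx="', num(xs[i]), '" cy="', num(ys[i]), '" r="',
            num(st$size / 2), '" fill="', st$fill_color, '"/>')
      else
        add('<rect x="', num(xs[i] - st$size / 2), '" y="',
            num(ys[i] - st$size / 2), '" width="', num(st$size),
            '" height="', num(st$size), '" fill="', st$fill_color, '"/>')
    }
    if (is_leaf(nd) && nzchar(nd$name))
      add('<text class="leaf" x="', num(xs[i] + 4), '" y="',
          num(ys[i] + 4), '" fill="', th$text, '">',
          xml_escape(nd$name), "</text>")
    # faces
    bx <- xs[i] + 4 + (if (is_leaf(nd)) 7 * nchar(nd$name) + 4 else 0)
    ax <- x_align
    for (f in lay[[i]]$faces) {
      fx <- switch(f$position, branch_right = bx, aligned_right = ax,
                   branch_top = if (!is.null(nd$parent))
                     (xs[pos_of(nd$parent)] + xs[i]) / 2 else xs[i])
      fy <- if (f$position == "branch_top") ys[i] - 4 else ys[i]
      if (f$kind == "text") {
        add('<text class="face" x="', num(fx), '" y="', num(fy + 4),
            '" fill="', th$text, '">', xml_escape(f$payload), "</text>")
        w <- 7 * nchar(f$payload) + 4
      } else if (f$kind == "sequence_strip") {
        res <- strsplit(f$payload, "")[[1L]]
        pal <- grDevices::rainbow(26, s = 0.35)
        for (k in seq_along(res)) {
          ch <- toupper(res[k])
          col <- if (ch %in% LETTERS) pal[match(ch, LETTERS)] else "#eeeeee"
          add('<rect class="residue" x="', num(fx + (k - 1) * 8), '" y="',
              num(fy - 6), '" width="8" height="12" fill="',
              substr(col, 1L, 7L), '"/>')
        }
        w <- 8 * length(res) + 4
      } else if (f$kind == "heatmap_row") {
        v <- f$payload
        for (k in seq_along(v)) {
          add('<rect class="heatcell" x="', num(fx + (k - 1) * 10), '" y="',
              num(fy - row_height / 2 + 1), '" width="10" height="',
              num(row_height - 2), '" fill="', heat_color(v[k], hlo, hhi),
              '"/>')
        }
        w <- 10 * length(v) + 4
      } else if (f$kind == "bar_graph") {
        v <- f$payload
        vmax <- max(abs(v), 1e-12)
        for (k in seq_along(v)) {
          h <- abs(v[k]) / vmax * row_height
          add('<rect class="bar" x="', num(fx + (k - 1) * 6), '" y="',
              num(fy - h / 2), '" width="5" height="', num(max(h, 0.5)),
              '" fill="#555555"/>')
        }
        w <- 6 * length(v) + 4
      } else if (f$kind == "external_image") {
        add('<image x="', num(fx), '" y="', num(fy - 8),
            '" width="16" height="16" href="', xml_escape(f$payload), '"/>')
        w <- 20
      } else w <- 0
      if (f$position == "branch_right") bx <- bx + w
      if (f$position == "aligned_right") ax <- ax + w
    }
  }
  n_leaves <- leaf_i
  total_w <- max(x_align + 300, max(xs) + 200)
  total_h <- 2 * margin + n_leaves * row_height
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<svg xmlns="http://www.w3.org/2000/svg" width="', num(total_w),
    '" height="', num(total_h), '" font-family="monospace" font-size="12">\n',
    paste(el, collapse = "\n"),
    "\n</svg>\n"
  )
}
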