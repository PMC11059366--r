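#' Deterministic 2D layout of a secondary structure
#'
#' Embeds the structure graph (backbone adjacencies plus base-pair bonds) in
#' the plane with the classic radial-loop drawing: every loop's members lie
#' on a circle, helices are drawn as two parallel strands, and exterior-loop
#' bases run along a straight line. Coordinates are rescaled so that the
#' mean distance between backbone-adjacent bases is exactly 1.0 -- the
#' "length unit" in which coverage-score radii are expressed.
#'
#' @param structure A [secondary_structure()].
#' @return Object of class `structure_layout`: list with `n`, `coords`
#'   (`n x 2` matrix), `pairs` (base-pair matrix) and `sequence`.
#' @examples
#' layout_2d(fold_baseline("GGGGAAAACCCC"))
#' @export
layout_2d <- function(structure) {
  stopifnot(inherits(structure, "secondary_structure"))
  n <- nchar(structure$sequence)
  partner <- partner_vector(structure)
  coords <- matrix(NA_real_, nrow = n, ncol = 2L)

  rot90 <- function(v) c(-v[2L], v[1L])
  # length of the maximal stack whose outer pair is (i, j)
  stack_len <- function(i, j) {
    h <- 1L
    while (i + h < j - h && partner[i + h] == j - h) h <- h + 1L
    h
  }

  # draw pairs 1..h-1 of a helix whose outer pair is already placed,
  # then lay out the loop it closes
  extend_helix <- function(p, q, h, dir) {
    w <- sqrt(sum((coords[q, ] - coords[p, ])^2))
    cm <- (coords[p, ] + coords[q, ]) / 2
    if (h > 1L) {
      perp <- rot90(dir)
      if (sum(perp * (coords[p, ] - coords[q, ])) < 0) perp <- -perp
      for (t in seq_len(h - 1L)) {
        centre <- cm + dir * t
        coords[p + t, ] <<- centre + perp * (w / 2)
        coords[q - t, ] <<- centre - perp * (w / 2)
      }
    }
    inner_i <- p + h - 1L
    inner_j <- q - h + 1L
    if (inner_j - inner_i > 1L) place_loop(inner_i, inner_j, dir)
  }

  # lay out the loop closed by pair (ci, cj) (both already placed),
  # entered travelling along `dir`
  place_loop <- function(ci, cj, dir) {
    members <- list()
    b <- ci + 1L
    while (b < cj) {
      if (partner[b] == 0L) {
        members[[length(members) + 1L]] <- list(kind = "base", at = b)
        b <- b + 1L
      } else {
        members[[length(members) + 1L]] <-
          list(kind = "helix", p = b, q = partner[b])
        b <- partner[b] + 1L
      }
    }
    k <- 2L + sum(vapply(members, function(m)
      if (m$kind == "base") 1L else 2L, integer(1)))
    R <- 1 / (2 * sin(pi / k))                 # unit chords between slots
    wc <- sqrt(sum((coords[cj, ] - coords[ci, ])^2))
    centre <- (coords[ci, ] + coords[cj, ]) / 2 +
      dir * sqrt(max(R^2 - (wc / 2)^2, 1e-4))
    ai <- atan2(coords[ci, 2L] - centre[2L], coords[ci, 1L] - centre[1L])
    aj <- atan2(coords[cj, 2L] - centre[2L], coords[cj, 1L] - centre[1L])
    delta <- 2 * pi / k
    circ_dist <- function(a, b) {
      d <- (a - b) %% (2 * pi)
      min(d, 2 * pi - d)
    }
    # one slot step from cj must land on ci: pick the traversal direction
    s <- if (circ_dist(aj - ai, -delta) <= circ_dist(aj - ai, delta)) 1 else -1
    slot_pos <- function(t) {
      a <- ai + s * delta * t
      centre + R * c(cos(a), sin(a))
    }
    t <- 1L
    for (m in members) {
      if (m$kind == "base") {
        coords[m$at, ] <<- slot_pos(t)
        t <- t + 1L
      } else {
        coords[m$p, ] <<- slot_pos(t)
        coords[m$q, ] <<- slot_pos(t + 1L)
        cm <- (coords[m$p, ] + coords[m$q, ]) / 2
        dir_out <- cm - centre
        dir_out <- dir_out / sqrt(sum(dir_out^2))
        extend_helix(m$p, m$q, stack_len(m$p, m$q), dir_out)
        t <- t + 2L
      }
    }
  }

  # exterior loop: a straight line, helices branching off perpendicular
  x <- 0
  b <- 1L
  while (b <= n) {
    if (partner[b] == 0L) {
      coords[b, ] <- c(x, 0)
      x <- x + 1
      b <- b + 1L
    } else {
      q <- partner[b]
      coords[b, ] <- c(x, 0)
      coords[q, ] <- c(x + 1, 0)
      extend_helix(b, q, stack_len(b, q), c(0, 1))
      x <- x + 3
      b <- q + 1L
    }
  }

  new_structure_layout(coords, structure$pairs, structure$sequence)
}

# rescale to mean unit backbone spacing and wrap
new_structure_layout <- function(coords, pairs, sequence = NULL) {
  n <- nrow(coords)
  if (any(!is.finite(coords))) stop("layout has non-finite coordinates",
                                    call. = FALSE)
  if (n > 1L) {
    d <- sqrt(rowSums((coords[-1L, , drop = FALSE] -
                         coords[-n, , drop = FALSE])^2))
    md <- mean(d)
    if (md <= 0) stop("degenerate layout: zero backbone spacing",
                      call. = FALSE)
    coords <- coords / md
  }
  colnames(coords) <- c("x", "y")
  structure(
    list(n = n, coords = coords, pairs = pairs, sequence = sequence),
    class = "structure_layout"
  )
}

#' @export
print.structure_layout <- function(x, ...) {
  cat(sprintf("<structure_layout> %d bases, %d pair bonds, unit backbone spacing\n",
              x$n, nrow(x$pairs)))
  invisible(x)
}

#' Write a structure layout as a GML graph
#'
#' Nodes are bases in backbone order, with `x`/`y` coordinates and the base
#' as `label`; edges are the backbone adjacencies and the base-pair bonds.
#'
#' @param layout A [layout_2d()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_gml <- function(layout, path) {
  stopifnot(inherits(layout, "structure_layout"))
  g <- layout_to_igraph(layout)
  igraph::write_graph(g, path, format = "gml")
  invisible(path)
}

layout_to_igraph <- function(layout) {
  n <- layout$n
  backbone <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  edges <- rbind(backbone, layout$pairs)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  igraph::V(g)$x <- layout$coords[, 1L]
  igraph::V(g)$y <- layout$coords[, 2L]
  if (!is.null(layout$sequence)) {
    igraph::V(g)$label <- strsplit(layout$sequence, "", fixed = TRUE)[[1L]]
  }
  g
}

#' Import a structure layout from a GML graph
#'
#' Reads a GML file whose nodes carry 2D coordinates (as produced by
#' [export_gml()], or by external structure-drawing tools when their
#' per-node coordinate blocks are flattened to `x`/`y` attributes). Node
#' file order is taken as backbone order; the backbone must form a complete
#' path. Coordinates are rescaled to unit mean backbone spacing.
#'
#' @param path GML file path.
#' @return A `structure_layout`.
#' @export
import_gml <- function(path) {
  lines <- readLines(path)
  # flatten one-line nested coordinate blocks (`graphics [ x .. y .. ]`,
  # `vertice [ x .. y .. ]`) into plain x/y node attributes
  flat <- gsub("(graphics|vertice)\\s*\\[\\s*x\\s+(\\S+)\\s+y\\s+(\\S+)\\s*\\]",
               "x \\2 y \\3", lines)
  src <- path
  if (!identical(flat, lines)) {
    src <- tempfile(fileext = ".gml")
    on.exit(unlink(src), add = TRUE)
    writeLines(flat, src)
  }
  g <- igraph::read_graph(src, format = "gml")
  va <- igraph::vertex_attr_names(g)
  if (!all(c("x", "y") %in% va)) {
    stop("GML file has no node coordinates (x/y)", call. = FALSE)
  }
  n <- igraph::vcount(g)
  coords <- cbind(igraph::V(g)$x, igraph::V(g)$y)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0L && n > 1L) {
    stop("GML backbone is not a complete path over the node order",
         call. = FALSE)
  }
  el <- t(apply(el, 1L, sort))
  is_backbone <- el[, 2L] - el[, 1L] == 1L
  have <- as.integer(sort(unique(el[is_backbone, 1L])))
  if (n > 1L && !identical(have, seq_len(n - 1L))) {
    stop("GML backbone is not a complete path over the node order",
         call. = FALSE)
  }
  pairs <- el[!is_backbone, , drop = FALSE]
  pairs <- unique(pairs[order(pairs[, 1L]), , drop = FALSE])
  colnames(pairs) <- c("i", "j")
  seq <- if ("label" %in% va) paste(igraph::V(g)$label, collapse = "") else NULL
  new_structure_layout(coords, pairs, seq)
}

#' Coverage score of a binding site in a 2D structure layout
#'
#' For each base of the site (the seed region on the target), counts the
#' layout vertices within a closed Euclidean ball of radius `r` length
#' units (the base itself included), then averages over the site bases:
#'
#' \deqn{\mathrm{cov}(S, r) = \frac{1}{|S|}\sum_{s \in S}\;
#'   \#\{v \in V : \lVert v - s\rVert_2 \le r\}}{
#'   cov(S, r) = (1/|S|) sum_s #\{v : ||v - s|| <= r\}}
#'
#' A low score means few bases crowd the site in the drawing -- an open,
#' accessible region; a high score means the site sits in a densely folded
#' neighbourhood.
#'
#' @param layout A [layout_2d()] or [import_gml()] result.
#' @param site One-row site table or numeric `c(start, end)`.
#' @param r Radius in length units (> 0). Membership on the ball boundary
#'   is decided with a 1e-9 tolerance.
#' @return Object of class `coverage_result`: list with `start`, `end`,
#'   `r`, `score` and `is_min_over_sites` (`FALSE` here).
#' @export
coverage_score <- function(layout, site, r) {
  stopifnot(inherits(layout, "structure_layout"))
  if (!is.numeric(r) || length(r) != 1L || r <= 0) {
    stop("radius r must be a positive number", call. = FALSE)
  }
  se <- site_span(site)
  if (se[1L] < 1L || se[2L] > layout$n || se[1L] > se[2L]) {
    stop("site is out of layout bounds", call. = FALSE)
  }
  idx <- se[1L]:se[2L]
  counts <- vapply(idx, function(s) {
    d2 <- (layout$coords[, 1L] - layout$coords[s, 1L])^2 +
      (layout$coords[, 2L] - layout$coords[s, 2L])^2
    sum(d2 <= (r + 1e-9)^2)
  }, numeric(1))
  structure(
    list(start = se[1L], end = se[2L], r = r,
         score = sum(counts) / length(idx),
         is_min_over_sites = FALSE),
    class = "coverage_result"
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> site [%d,%d], r = %g: score %.3f%s\n",
              x$start, x$end, x$r, x$score,
              if (isTRUE(x$is_min_over_sites)) " (minimum over sites)" else ""))
  invisible(x)
}

#' Most accessible site: minimum coverage over candidate sites
#'
#' When a fragment carries several seed-match sites, the site with the
#' smallest coverage score -- the most accessible one -- represents the
#' fragment. Ties resolve to the 5'-most site.
#'
#' @param layout A `structure_layout`.
#' @param sites Site table from [find_seed_sites()] (>= 1 row).
#' @param r Radius in length units.
#' @return A `coverage_result` with `is_min_over_sites = TRUE` and the
#'   selected site's row index attached as attribute `"site_index"`.
#' @export
min_coverage_over_sites <- function(layout, sites, r) {
  stopifnot(is.data.frame(sites))
  if (nrow(sites) == 0L) {
    stop("at least one site is required", call. = FALSE)
  }
  results <- lapply(seq_len(nrow(sites)), function(k) {
    coverage_score(layout, sites[k, , drop = FALSE], r)
  })
  scores <- vapply(results, function(x) x$score, numeric(1))
  starts <- vapply(results, function(x) x$start, numeric(1))
  best <- order(scores, starts)[1L]
  out <- results[[best]]
  out$is_min_over_sites <- TRUE
  attr(out, "site_index") <- best
  out
}

#' Default radius sweep for coverage-score analyses
#'
#' Radii from 0.8 to 6 length units, spanning nearest-neighbour contact
#' (below unit backbone spacing) up to a broad structural neighbourhood.
#'
#' @return Numeric vector of radii.
#' @export
default_radii <- function() c(0.8, 1, 1.5, 2, 2.5, 3, 4, 5, 6)
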