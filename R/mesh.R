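#' Generate a Voronoi confinement mesh ("actin corrals")
#'
#' Emulates the submembranous actin meshwork as a Voronoi tessellation of
#' randomly seeded points inside a circular arena. Seeds are drawn from a
#' homogeneous Poisson point process whose intensity is chosen so that the
#' mean nearest-neighbour seed distance equals `seed_spacing`
#' (`lambda = (0.5 / seed_spacing)^2`, since the mean nearest-neighbour
#' distance of a Poisson process of intensity lambda is `0.5 / sqrt(lambda)`).
#' Voronoi tiles are clipped to the circular arena, and the mesh size is
#' summarised as the square root of the mean compartment area.
#'
#' @param seed_spacing target mean nearest-neighbour seed distance (nm).
#' @param arena_diameter diameter of the circular arena (nm).
#' @param rng_seed optional integer seed for reproducibility.
#' @return an object of class `corral_mesh`: a list with `seeds` (tibble of
#'   seed coordinates in nm), `compartments` (list of polygon tibbles clipped
#'   to the arena), `areas` (nm^2), `mesh_size` (nm, `sqrt(mean(areas))`),
#'   `arena_diameter` and `seed_spacing`.
#' @examples
#' mesh <- generate_corral_mesh(seed_spacing = 200, arena_diameter = 3000,
#'                              rng_seed = 1)
#' mesh$mesh_size
#' @export
generate_corral_mesh <- function(seed_spacing, arena_diameter, rng_seed = NULL) {
  stopifnot(seed_spacing > 0, arena_diameter > 0)
  if (seed_spacing >= arena_diameter / 4) {
    abort("`seed_spacing` must be smaller than `arena_diameter` / 4.")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  radius <- arena_diameter / 2
  lambda <- (0.5 / seed_spacing)^2       # points per nm^2
  n <- rpois(1, lambda * pi * radius^2)
  if (n < 3) {
    abort(sprintf(
      "Degenerate mesh: only %d seed(s) generated; need at least 3.", n))
  }
  # uniform points in the disc
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  corral_mesh_from_seeds(
    tibble(x = r * cos(th), y = r * sin(th)),
    arena_diameter = arena_diameter, seed_spacing = seed_spacing)
}

#' Build a corral mesh from explicit seed points
#'
#' Constructs the Voronoi compartments (clipped to the circular arena) for a
#' given set of seed points. Unlike [generate_corral_mesh()], one or two
#' seeds are allowed: a single seed yields the whole arena as one
#' compartment.
#'
#' @param seeds data frame with columns `x`, `y` (nm, arena-centred).
#' @param arena_diameter arena diameter (nm).
#' @param seed_spacing optional nominal spacing recorded in the object (nm).
#' @return a `corral_mesh` object; see [generate_corral_mesh()].
#' @export
corral_mesh_from_seeds <- function(seeds, arena_diameter, seed_spacing = NA_real_) {
  seeds <- as_tibble(seeds)
  stopifnot(all(c("x", "y") %in% names(seeds)), nrow(seeds) >= 1)
  radius <- arena_diameter / 2
  if (any(seeds$x^2 + seeds$y^2 > radius^2)) {
    abort("All seed points must lie inside the arena.")
  }
  circ <- circle_polygon(radius)
  n <- nrow(seeds)
  if (n == 1) {
    polys <- list(circ)
  } else if (n == 2) {
    polys <- lapply(1:2, function(i) {
      j <- 3 - i
      # keep points closer to seed i than to seed j:
      # 2(xj-xi)x + 2(yj-yi)y <= xj^2+yj^2-xi^2-yi^2
      a <- 2 * (seeds$x[j] - seeds$x[i]); b <- 2 * (seeds$y[j] - seeds$y[i])
      cc <- seeds$x[j]^2 + seeds$y[j]^2 - seeds$x[i]^2 - seeds$y[i]^2
      clip_halfplane(circ$x, circ$y, a, b, cc)
    })
  } else {
    dd <- deldir::deldir(seeds$x, seeds$y,
                         rw = c(-radius, radius, -radius, radius))
    tl <- deldir::tile.list(dd)
    r2 <- radius^2
    polys <- lapply(tl, function(tile) {
      if (all(tile$x^2 + tile$y^2 <= r2)) {
        list(x = tile$x, y = tile$y)
      } else {
        clip_convex(tile$x, tile$y, circ$x, circ$y)
      }
    })
    # tile.list is ordered by input point index (ptNum), but be defensive
    ord <- vapply(tl, function(t) t$ptNum, numeric(1))
    polys <- polys[order(ord)]
  }
  areas <- vapply(polys, function(p) polygon_area(p$x, p$y), numeric(1))
  structure(list(
    seeds = seeds,
    compartments = lapply(polys, function(p) tibble(x = p$x, y = p$y)),
    areas = areas,
    mesh_size = sqrt(mean(areas)),
    arena_diameter = arena_diameter,
    seed_spacing = seed_spacing
  ), class = "corral_mesh")
}

#' @export
print.corral_mesh <- function(x, ...) {
  cat(sprintf(
    "<corral_mesh> %d compartments, arena %.0f nm, mesh size %.1f nm (sqrt mean area)\n",
    length(x$areas), x$arena_diameter, x$mesh_size))
  invisible(x)
}

#' Pool the mesh-size statistic over mesh realizations
#'
#' The mesh size of a set of independent meshes is summarised as the square
#' root of the mean compartment area pooled over all compartments of all
#' realizations.
#'
#' @param meshes a list of `corral_mesh` objects.
#' @return pooled mesh size (nm).
#' @export
pooled_mesh_size <- function(meshes) {
  stopifnot(length(meshes) >= 1)
  sqrt(mean(unlist(lapply(meshes, `[[`, "areas"))))
}

#' Compartment membership by nearest seed
#'
#' Resolves which Voronoi compartment each query point belongs to via
#' nearest-seed lookup (equivalent to Voronoi containment; ties broken by
#' lowest seed index).
#'
#' @param mesh a `corral_mesh`.
#' @param x,y query coordinates (nm).
#' @return integer vector of compartment indices.
#' @export
compartment_of <- function(mesh, x, y) {
  cell <- grid_cell_size(mesh)
  cpp_nearest_seed(as.numeric(x), as.numeric(y),
                   mesh$seeds$x, mesh$seeds$y, cell)
}

# grid cell size for the nearest-seed index: ~2x the typical seed spacing
grid_cell_size <- function(mesh) {
  sp <- mesh$seed_spacing
  if (is.na(sp) || !is.finite(sp) || sp <= 0) {
    sp <- sqrt(pi * (mesh$arena_diameter / 2)^2 / nrow(mesh$seeds)) / 2
  }
  max(2 * sp, mesh$arena_diameter / 200)
}

#' Plot a corral mesh
#'
#' @param object a `corral_mesh`.
#' @param ... unused.
#' @return a ggplot object showing compartment polygons and seed points.
#' @method autoplot corral_mesh
#' @export
autoplot.corral_mesh <- function(object, ...) {
  poly_df <- dplyr::bind_rows(
    lapply(seq_along(object$compartments), function(i) {
      dplyr::mutate(object$compartments[[i]], compartment = i)
    }))
  ggplot2::ggplot(poly_df, ggplot2::aes(x = .data$x, y = .data$y,
                                        group = .data$compartment)) +
    ggplot2::geom_polygon(fill = NA, colour = "grey40", linewidth = 0.2) +
    ggplot2::geom_point(data = object$seeds, inherit.aes = FALSE,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 0.3, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)",
                  title = sprintf("Confinement mesh, mesh size %.0f nm",
                                  object$mesh_size))
}
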