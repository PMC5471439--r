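#' Imaging volume geometry
#'
#' The sampled test volume in which labeled cells are counted. Defaults match
#' the confocal acquisition this package emulates: a 350 x 350 um field imaged
#' at 1-um z-increments through 100 um of tissue, isotropic 1-um voxels.
#'
#' @param x_extent,y_extent,z_extent Extents in um.
#' @param voxel_size Isotropic voxel edge in um; extents must be integer
#'   multiples of it.
#' @return An object of class `imaging_volume`.
#' @export
imaging_volume <- function(x_extent = 350, y_extent = 350, z_extent = 100,
                           voxel_size = 1) {
  for (nm in c("x_extent", "y_extent", "z_extent", "voxel_size"))
    check_number(get(nm), nm, positive = TRUE)
  dims <- c(x_extent, y_extent, z_extent) / voxel_size
  if (any(abs(dims - round(dims)) > 1e-8))
    stop_arg("extents must be integer multiples of voxel_size")
  structure(list(x_extent = x_extent, y_extent = y_extent,
                 z_extent = z_extent, voxel_size = voxel_size,
                 dim = as.integer(round(dims))),
            class = "imaging_volume")
}

#' Place non-overlapping cells in an imaging volume
#'
#' Draws soma areas from the area model, converts them to ellipsoid radii
#' (equatorial radii `a = b = sqrt(area/pi)` so the maximal cross-section
#' equals the drawn area; polar radius `c = c_ratio * a`), and places the
#' cells uniformly at random so that every ellipsoid lies fully inside the
#' volume and no two bounding spheres come closer than `margin` um. Uniform
#' placement is a modeling choice: the true within-volume spatial pattern of
#' labeled cells is unknown.
#'
#' @param n_neurons,n_glia Number of cells per class.
#' @param volume An [imaging_volume()].
#' @param model An [area_model()].
#' @param c_ratio Polar-to-equatorial radius ratio of the soma ellipsoids.
#' @param margin Minimum clearance between bounding spheres, um (default 3,
#'   about 3x the typical PSF sigma, so that blurred neighbors remain
#'   resolvable as separate objects).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling attempts per cell before giving up.
#' @return Data frame with columns `cell_id`, `x`, `y`, `z` (centroid, um),
#'   `a`, `b`, `c` (radii, um), `true_class`, `true_area_um2` (analytic
#'   maximal cross-section `pi*a*b`).
#' @export
place_cells <- function(n_neurons, n_glia, volume = imaging_volume(),
                        model = area_model(), c_ratio = 0.8, margin = 3,
                        seed = NULL, max_tries = 2000) {
  if (!inherits(volume, "imaging_volume"))
    stop_arg("`volume` must be an imaging_volume")
  check_number(c_ratio, "c_ratio", positive = TRUE)
  check_number(margin, "margin", nonneg = TRUE)
  areas <- generate_soma_areas(n_neurons, n_glia, model, seed = seed)
  n <- nrow(areas)
  a <- sqrt(areas$area_um2 / pi)
  cc <- c_ratio * a
  rad <- pmax(a, cc)  # bounding-sphere radius
  with_seed_or_current(if (is.null(seed)) NULL else seed + 1L, {
    xs <- ys <- zs <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        px <- runif(1, rad[i], volume$x_extent - rad[i])
        py <- runif(1, rad[i], volume$y_extent - rad[i])
        pz <- runif(1, cc[i], volume$z_extent - cc[i])
        if (i == 1L) { ok <- TRUE } else {
          j <- seq_len(i - 1L)
          d2 <- (xs[j] - px)^2 + (ys[j] - py)^2 + (zs[j] - pz)^2
          ok <- all(d2 >= (rad[j] + rad[i] + margin)^2)
        }
        if (ok) { xs[i] <- px; ys[i] <- py; zs[i] <- pz; break }
      }
      if (!ok)
        stop_arg("could not place %d non-overlapping cells in the volume (stuck at cell %d); use a larger volume or fewer cells",
                 n, i)
    }
    data.frame(cell_id = seq_len(n), x = xs, y = ys, z = zs,
               a = a, b = a, c = cc,
               true_class = areas$true_class,
               true_area_um2 = pi * a * a,
               stringsAsFactors = FALSE)
  })
}

#' Render a synthetic fluorescence image stack
#'
#' Renders each cell as a solid axis-aligned ellipsoid of unit amplitude on a
#' dark background, optionally applies an isotropic Gaussian blur (separable,
#' edge-renormalized) emulating the microscope PSF, and, when
#' `noise_scale > 0`, replaces each voxel value by a Poisson draw with rate
#' `amplitude * noise_scale` (shot noise at that photon budget). Noise-free
#' stacks are stored as 16-bit integers (0 or 65535 before blur).
#'
#' @param cells Data frame as returned by [place_cells()] (columns `x`, `y`,
#'   `z`, `a`, `b`, `c`, `true_class`; `true_area_um2` optional, recomputed as
#'   `pi*a*b` if missing). All centroids must lie inside the volume.
#' @param volume An [imaging_volume()].
#' @param blur_sigma Gaussian blur sigma in um (0 = no blur).
#' @param noise_scale Mean photon count in fully labeled voxels (0 = no
#'   noise).
#' @param seed Integer seed (used only when `noise_scale > 0`).
#' @return An object of class `synthetic_stack`: list with `intensities`
#'   (integer array, dim = volume$dim, x-y-z order), `ground_truth` (the cell
#'   table with `true_area_um2`), `volume`, `blur_sigma`, `noise_scale`,
#'   `seed`.
#' @export
render_stack <- function(cells, volume = imaging_volume(), blur_sigma = 0,
                         noise_scale = 0, seed = NULL) {
  if (!inherits(volume, "imaging_volume"))
    stop_arg("`volume` must be an imaging_volume")
  check_number(blur_sigma, "blur_sigma", nonneg = TRUE)
  check_number(noise_scale, "noise_scale", nonneg = TRUE)
  req <- c("x", "y", "z", "a", "b", "c", "true_class")
  if (!is.data.frame(cells) || !all(req %in% names(cells)))
    stop_arg("`cells` must be a data frame with columns %s",
             paste(req, collapse = ", "))
  if (nrow(cells) > 0) {
    if (any(cells$a <= 0 | cells$b <= 0 | cells$c <= 0))
      stop_arg("cell radii must be positive")
    inside <- cells$x >= 0 & cells$x <= volume$x_extent &
      cells$y >= 0 & cells$y <= volume$y_extent &
      cells$z >= 0 & cells$z <= volume$z_extent
    if (!all(inside))
      stop_arg("%d cell centroid(s) lie outside the imaging volume",
               sum(!inside))
  }
  if (is.null(cells$true_area_um2))
    cells$true_area_um2 <- pi * cells$a * cells$b
  if (is.null(cells$cell_id)) cells$cell_id <- seq_len(nrow(cells))

  vs <- volume$voxel_size
  dims <- volume$dim
  amp <- array(0, dim = dims)
  for (i in seq_len(nrow(cells))) {
    # voxel-center coordinates: voxel k spans [(k-1)*vs, k*vs], center (k-0.5)*vs
    ix <- max(1L, floor((cells$x[i] - cells$a[i]) / vs)):
      min(dims[1], ceiling((cells$x[i] + cells$a[i]) / vs) + 1L)
    iy <- max(1L, floor((cells$y[i] - cells$b[i]) / vs)):
      min(dims[2], ceiling((cells$y[i] + cells$b[i]) / vs) + 1L)
    iz <- max(1L, floor((cells$z[i] - cells$c[i]) / vs)):
      min(dims[3], ceiling((cells$z[i] + cells$c[i]) / vs) + 1L)
    dx2 <- (((ix - 0.5) * vs - cells$x[i]) / cells$a[i])^2
    dy2 <- (((iy - 0.5) * vs - cells$y[i]) / cells$b[i])^2
    dz2 <- (((iz - 0.5) * vs - cells$z[i]) / cells$c[i])^2
    box <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
    sub <- amp[ix, iy, iz, drop = FALSE]
    sub[box] <- 1
    amp[ix, iy, iz] <- sub
  }
  if (blur_sigma > 0 && nrow(cells) > 0)
    amp <- gaussian_blur_3d(amp, blur_sigma / vs)

  intens <- if (noise_scale > 0) {
    with_seed_or_current(seed, array(rpois(length(amp), amp * noise_scale),
                                     dim = dims))
  } else {
    array(as.integer(round(amp * 65535)), dim = dims)
  }
  structure(list(intensities = intens, ground_truth = cells, volume = volume,
                 blur_sigma = blur_sigma, noise_scale = noise_scale,
                 seed = seed),
            class = "synthetic_stack")
}

# Separable 3-D Gaussian blur via sparse banded convolution matrices; kernel
# truncated at 3 sigma and renormalized at the array edges (each output voxel
# is a convex combination of inputs).
gaussian_blur_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- dnorm(seq(-r, r), sd = sigma_vox)
  band_mat <- function(n) {
    i <- rep(seq_len(n), each = 2L * r + 1L)
    j <- i + rep(seq(-r, r), times = n)
    w <- rep(k, times = n)
    keep <- j >= 1L & j <= n
    m <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = w[keep],
                              dims = c(n, n))
    m / Matrix::rowSums(m)
  }
  # blur along x: arr viewed as (d1) x (d2*d3)
  m1 <- band_mat(d[1])
  arr <- array(as.matrix(m1 %*% matrix(arr, d[1])), d)
  # along y
  m2 <- band_mat(d[2])
  arr <- aperm(array(as.matrix(m2 %*% matrix(aperm(arr, c(2, 1, 3)), d[2])),
                     d[c(2, 1, 3)]), c(2, 1, 3))
  # along z
  m3 <- band_mat(d[3])
  arr <- aperm(array(as.matrix(m3 %*% matrix(aperm(arr, c(3, 1, 2)), d[3])),
                     d[c(3, 1, 2)]), c(2, 3, 1))
  arr
}

#' @export
print.synthetic_stack <- function(x, ...) {
  cat(sprintf("Synthetic image stack: %d x %d x %d voxels (%g um voxel), %d cells, blur %g um, noise scale %g\n",
              x$volume$dim[1], x$volume$dim[2], x$volume$dim[3],
              x$volume$voxel_size, nrow(x$ground_truth), x$blur_sigma,
              x$noise_scale))
  invisible(x)
}

#' Write / read a synthetic stack as multi-page TIFF
#'
#' Pages are z-planes (row = y, column = x), 16-bit grayscale. Values are
#' clipped to 0..65535. An optional sidecar CSV stores the ground truth
#' (cell_id, x, y, z, true_class, true_area_um2).
#'
#' @param stack A `synthetic_stack`.
#' @param tiff_path Output TIFF path.
#' @param truth_csv Optional path for the ground-truth sidecar CSV.
#' @return `write_stack()` returns `tiff_path` invisibly; `read_stack()`
#'   returns an integer intensity array in x-y-z order (16-bit scale).
#' @export
write_stack <- function(stack, tiff_path, truth_csv = NULL) {
  if (!inherits(stack, "synthetic_stack"))
    stop_arg("`stack` must be a synthetic_stack")
  v <- pmin(pmax(stack$intensities, 0), 65535) / 65535
  pages <- lapply(seq_len(dim(v)[3]), function(z) t(v[, , z]))
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16,
                  compression = "none")
  if (!is.null(truth_csv)) {
    gt <- stack$ground_truth[c("cell_id", "x", "y", "z", "true_class",
                               "true_area_um2")]
    write.csv(gt, truth_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(tiff_path)
}

#' @rdname write_stack
#' @param path TIFF path to read.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 0) stop_arg("empty TIFF stack: %s", path)
  arr <- array(0L, dim = c(ncol(pages[[1]]), nrow(pages[[1]]),
                           length(pages)))
  for (z in seq_along(pages))
    arr[, , z] <- as.integer(round(t(pages[[z]]) * 65535))
  arr
}
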