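# K-means++ seeding: spread initial centroids with probability
# proportional to squared distance from the nearest chosen centre.
kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  if (K > 1L) for (j in 2:K) {
    if (all(d2 == 0)) {
      centers[j, ] <- X[sample.int(n, 1L), ]
    } else {
      pick <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- X[pick, ]
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

#' Derive ecoregions from climate normals by K-means
#'
#' Clusters grid cells of 30-year normal temperature, precipitation and
#' elevation into K discrete ecoregions. Variables are standardized
#' before clustering (their units differ by orders of magnitude), and
#' K-means runs with k-means++ initialization and multiple restarts
#' under a fixed seed so refits reproduce centroids exactly. K is fixed
#' by configuration (default 9); elbow diagnostics over a K range can be
#' requested but never change the fitted K.
#'
#' @param grid data.frame with `temp`, `precip`, `elev` (and usually
#'   `lat`, `lon`) columns, one row per grid cell.
#' @param K number of regions (default 9).
#' @param seed RNG seed for initialization.
#' @param nstart number of k-means++ restarts (default 25).
#' @param diagnostics if `TRUE`, also compute total within-cluster sum of
#'   squares for K = 1..max(12, K) as an elbow diagnostic.
#' @return object of class `ecoregion_model`: `K`, `centroids`
#'   (standardized space), `scaler` (per-variable mean/sd), `labels`,
#'   `inertia`, `sizes`, optional `diagnostics`.
#' @export
fit_ecoregions <- function(grid, K = 9L, seed = 1L, nstart = 25L,
                           diagnostics = FALSE) {
  X0 <- as.matrix(grid[, env_vars])
  if (!all(is.finite(X0))) stop("climate grid contains non-finite values")
  ndist <- nrow(unique(X0))
  if (K > ndist) stop("K = ", K, " exceeds the ", ndist,
                      " distinct grid points")
  mu <- colMeans(X0)
  sd_ <- apply(X0, 2L, stats::sd)
  sd_[sd_ == 0] <- 1
  X <- sweep(sweep(X0, 2L, mu), 2L, sd_, "/")

  set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    init <- kmeanspp_init(X, K)
    fit <- tryCatch(stats::kmeans(X, centers = init, iter.max = 100L),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss))
      best <- fit
  }
  if (is.null(best)) stop("k-means failed for every restart")
  # stable ordering: regions sorted by centroid temperature then precip
  ord <- order(best$centers[, 1], best$centers[, 2])
  centroids <- best$centers[ord, , drop = FALSE]
  relabel <- match(seq_len(K), ord)
  labels <- paste0("region_", seq_len(K))
  rownames(centroids) <- labels
  diag_tab <- NULL
  if (diagnostics) {
    ks <- seq_len(max(12L, K))
    ks <- ks[ks <= ndist]
    diag_tab <- data.frame(K = ks, inertia = vapply(ks, function(k) {
      set.seed(seed)
      f <- stats::kmeans(X, centers = kmeanspp_init(X, k), iter.max = 100L)
      f$tot.withinss
    }, numeric(1)))
  }
  structure(list(K = K, centroids = centroids,
                 scaler = list(mean = mu, sd = sd_),
                 labels = labels, inertia = best$tot.withinss,
                 sizes = as.integer(table(relabel[best$cluster])),
                 diagnostics = diag_tab),
            class = "ecoregion_model")
}

#' @export
print.ecoregion_model <- function(x, ...) {
  cat(sprintf("ecoregion model: K = %d, inertia = %.2f\n", x$K, x$inertia))
  invisible(x)
}

#' Nearest-centroid region of climate values
#'
#' @param model an [fit_ecoregions()] model.
#' @param newdata data.frame with `temp`, `precip`, `elev`.
#' @return character vector of region labels; ties go to the lowest
#'   region index.
#' @export
predict_ecoregion <- function(model, newdata) {
  X <- sweep(sweep(as.matrix(newdata[, env_vars]), 2L, model$scaler$mean),
             2L, model$scaler$sd, "/")
  d2 <- sapply(seq_len(model$K), function(k)
    rowSums(sweep(X, 2L, model$centroids[k, ])^2))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1L)
  model$labels[apply(d2, 1L, which.min)]
}

#' Assign animals to ecoregions through the climate grid
#'
#' Rounds each animal's coordinates (or its zip's grid cells) to the
#' nearest 0.1 degree (half away from zero) and looks the cell up in the
#' climate grid. Zips whose cells fall in more than one region are
#' flagged: those animals are excluded from discrete region analyses but
#' keep their (cell-averaged) continuous environmental values. Off-grid
#' locations stay unassigned. Every sample ends up in exactly one of the
#' three states: assigned, excluded (multi-region zip), or off-grid.
#'
#' @param samples data.frame with `id` and either `lat`/`lon` or a `zip`
#'   column resolvable through `zip_table`.
#' @param model an [fit_ecoregions()] model.
#' @param grid the climate grid the model was fitted to (`lat`, `lon`,
#'   `temp`, `precip`, `elev`).
#' @param zip_table optional data.frame `zip`, `lat`, `lon` (a zip may
#'   map to several cells).
#' @return `samples` with added columns `temp`, `precip`, `elev`,
#'   `ecoregion` (NA when excluded or off-grid), `excluded_discrete`,
#'   `off_grid`.
#' @export
assign_ecoregion <- function(samples, model, grid, zip_table = NULL) {
  grid <- as.data.frame(grid)
  gkey <- paste(round_half_up(grid$lat), round_half_up(grid$lon))
  grid_region <- predict_ecoregion(model, grid)

  lookup_cells <- function(lat, lon) {
    key <- paste(round_half_up(lat), round_half_up(lon))
    match(key, gkey)
  }

  n <- nrow(samples)
  temp <- precip <- elev <- rep(NA_real_, n)
  region <- rep(NA_character_, n)
  excluded <- rep(FALSE, n)
  off <- rep(FALSE, n)

  for (i in seq_len(n)) {
    if (!is.null(zip_table) && !is.null(samples$zip) &&
        !is.na(samples$zip[i]) && samples$zip[i] %in% zip_table$zip) {
      cells <- lookup_cells(zip_table$lat[zip_table$zip == samples$zip[i]],
                            zip_table$lon[zip_table$zip == samples$zip[i]])
      cells <- cells[!is.na(cells)]
    } else if (!is.null(samples$lat) && !is.na(samples$lat[i])) {
      cells <- lookup_cells(samples$lat[i], samples$lon[i])
      cells <- cells[!is.na(cells)]
    } else cells <- integer()
    if (length(cells) == 0L) { off[i] <- TRUE; next }
    temp[i] <- mean(grid$temp[cells])
    precip[i] <- mean(grid$precip[cells])
    elev[i] <- mean(grid$elev[cells])
    regs <- unique(grid_region[cells])
    if (length(regs) > 1L) excluded[i] <- TRUE else region[i] <- regs
  }
  if (any(off)) message("assign_ecoregion: ", sum(off), " sample(s) off-grid")
  if (any(excluded))
    message("assign_ecoregion: ", sum(excluded),
            " sample(s) excluded from discrete analyses (multi-region zip)")
  out <- samples
  out$temp <- temp; out$precip <- precip; out$elev <- elev
  out$ecoregion <- region
  out$excluded_discrete <- excluded
  out$off_grid <- off
  out
}

#' Serialize / restore an ecoregion model as JSON
#'
#' @param model an `ecoregion_model`.
#' @param path JSON file path.
#' @return `path` (write) or the restored model (read).
#' @export
write_ecoregion_model <- function(model, path) {
  obj <- list(K = model$K, centroids = model$centroids,
              scaler_mean = model$scaler$mean, scaler_sd = model$scaler$sd,
              labels = model$labels, inertia = model$inertia,
              sizes = model$sizes)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_ecoregion_model
#' @export
read_ecoregion_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cent <- matrix(unlist(obj$centroids), nrow = obj$K, byrow = FALSE)
  if (is.matrix(obj$centroids)) cent <- obj$centroids
  colnames(cent) <- env_vars
  rownames(cent) <- obj$labels
  structure(list(K = obj$K, centroids = cent,
                 scaler = list(mean = stats::setNames(unlist(obj$scaler_mean), env_vars),
                               sd = stats::setNames(unlist(obj$scaler_sd), env_vars)),
                 labels = obj$labels, inertia = obj$inertia,
                 sizes = obj$sizes, diagnostics = NULL),
            class = "ecoregion_model")
}

#' Synthetic climate grid with known region structure
#'
#' Generates a Gaussian-blob climate grid for testing: `n_regions`
#' spatially contiguous blocks of cells, each with its own climate
#' centroid separated by `separation` within-region standard deviations,
#' plus a zip table mapping synthetic zips to cells. A configurable
#' fraction of zips straddle two adjacent cells so the multi-region
#' exclusion rule can be exercised.
#'
#' @param n_regions number of true regions (default 9).
#' @param cells_per_region grid cells per region (default 60).
#' @param separation distance between region centroids in units of the
#'   within-region SD (default 6).
#' @param frac_straddle_zips fraction of zips spanning two cells
#'   (default 0.05).
#' @param seed RNG seed.
#' @return list: `grid` (lat, lon, temp, precip, elev), `truth` (true
#'   region per cell), `zips` (zip, lat, lon).
#' @export
synthetic_environment <- function(n_regions = 9L, cells_per_region = 60L,
                                  separation = 6, frac_straddle_zips = 0.05,
                                  seed = 1L) {
  set.seed(seed)
  n <- n_regions * cells_per_region
  # contiguous latitude bands, longitudes on a 0.1-degree lattice
  lat0 <- 30; lon0 <- -110
  per_row <- 37L   # deliberately coprime with typical region sizes so
                   # region boundaries fall inside rows and straddling
                   # zips can span them
  idx <- seq_len(n) - 1L
  lat <- lat0 + (idx %/% per_row) * 0.1
  lon <- lon0 + (idx %% per_row) * 0.1
  truth <- rep(seq_len(n_regions), each = cells_per_region)

  # centers: sphered so the center cloud is isotropic (per-variable
  # standardization downstream then shrinks all axes alike), scaled so
  # the minimum pairwise distance equals `separation` in within-region
  # SD units -- "separation" then means separation
  # per-axis variances of the center cloud are equalized so that the
  # per-variable standardization done at fit time shrinks every axis by
  # the same factor and the separation-to-noise ratio survives intact
  centers <- matrix(stats::rnorm(n_regions * 3), n_regions, 3)
  if (n_regions > 1L) {
    cc <- scale(centers)
    cc[is.nan(cc)] <- 0
    dmin <- min(stats::dist(cc))
    centers <- cc / dmin * separation
  }
  z <- centers[truth, , drop = FALSE] + matrix(stats::rnorm(n * 3), n, 3)
  # map to climate units via the column-standardized field so the
  # physical ranges stay plausible whatever the separation; the rare
  # tail clamp (> 3 SD) does not touch cluster geometry
  zt <- scale(z)
  zt[is.nan(zt)] <- 0
  grid <- data.frame(lat = round_half_up(lat), lon = round_half_up(lon),
                     temp = 12 + 8 * zt[, 1],
                     precip = pmax(1000 + 300 * zt[, 2], 0),
                     elev = pmax(600 + 250 * zt[, 3], 0))
  n_straddle <- round(frac_straddle_zips * n / 2)
  # prefer pairs that span a region boundary so the multi-region-zip
  # exclusion rule has something to catch
  eligible <- which(seq_len(n) %% per_row != 0L & seq_len(n) < n)
  boundary <- eligible[truth[eligible] != truth[eligible + 1L]]
  interior <- setdiff(eligible, boundary)
  straddle_first <- if (n_straddle > 0) {
    c(boundary[seq_len(min(length(boundary), n_straddle))],
      if (n_straddle > length(boundary))
        sample(interior, n_straddle - length(boundary)))
  } else integer()
  zip_of_cell <- rep(NA_character_, n)
  zcount <- 0L
  zips <- list()
  for (i in seq_len(n)) {
    if (!is.na(zip_of_cell[i])) next
    zcount <- zcount + 1L
    zid <- sprintf("z%05d", zcount)
    cells <- i
    if (i %in% straddle_first) cells <- c(i, i + 1L)
    zip_of_cell[cells] <- zid
    zips[[zcount]] <- data.frame(zip = zid, lat = grid$lat[cells],
                                 lon = grid$lon[cells])
  }
  list(grid = grid, truth = truth, zips = do.call(rbind, zips))
}
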