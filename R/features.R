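# Fixed-length topological feature vectors from persistent-Laplacian
# spectra of element/site-specific point clouds.

#' Summary statistics of a Laplacian spectrum
#'
#' Splits the spectrum into its harmonic part (eigenvalues below the zero
#' tolerance) and non-harmonic part, and returns the harmonic multiplicity
#' together with min, max, mean, standard deviation, sum and variance of the
#' non-harmonic eigenvalues (population moments) plus a presence flag that
#' is zero when there are no non-harmonic eigenvalues.
#'
#' @param spec A `LaplacianSpectrum`.
#' @return Named numeric vector of length 8: `n_harmonic`, `nh_min`,
#'   `nh_max`, `nh_mean`, `nh_sd`, `nh_sum`, `nh_var`, `nh_present`.
#' @export
spectral_statistics <- function(spec) {
  ev <- spec$eigenvalues
  nh <- ev[ev >= spec$zero_tol]
  if (length(nh) == 0) {
    out <- c(length(ev), 0, 0, 0, 0, 0, 0, 0)
  } else {
    v <- mean((nh - mean(nh))^2)
    out <- c(length(ev) - length(nh), min(nh), max(nh), mean(nh), sqrt(v),
             sum(nh), v, 1)
  }
  names(out) <- c("n_harmonic", "nh_min", "nh_max", "nh_mean", "nh_sd",
                  "nh_sum", "nh_var", "nh_present")
  out
}

#' Feature configuration
#'
#' Declares the subset roster and filtration grids from which
#' [filtration_features()] builds its vector. The defaults use all ordered
#' element pairs from carbon, nitrogen and oxygen on both site types
#' (mutation-centric and binding-interface), a dimension-0 Vietoris-Rips
#' grid of 0-12 angstrom in steps of 0.25, and dimension-1/2 Alpha grids of
#' 0-12 angstrom in steps of 0.5, with a persistence offset of one grid
#' step.
#'
#' @param elements Element symbols forming the pair roster.
#' @param site_types Subset families: `"mutation"` (mutation site vs
#'   neighborhood) and/or `"binding"` (partner 1 vs partner 2 interface).
#' @param r_mut,r_bind Cutoff radii in angstrom for the neighborhood and
#'   binding-site subsets.
#' @param grid0 Filtration grid (angstrom) for dimension 0 (Rips diameter
#'   scale).
#' @param grid12 Filtration grid (angstrom) for dimensions 1-2 (Alpha radius
#'   scale).
#' @param dims Laplacian dimensions to featurize (subset of 0:2).
#' @param mode0 Distance mode for the dimension-0 Rips complex:
#'   `"mod"` (cross-group only, the default) or `"euclidean"`.
#' @param alpha_prune Apply the cross-group exclusion to the Alpha complex
#'   by pruning same-group simplices. Default `FALSE`: the Alpha complex is
#'   kept Euclidean so that dimension-2 cavities remain possible (with two
#'   groups, pruning leaves no simplex above dimension 1).
#' @param persistence `"step"` for a persistence offset of one grid step,
#'   or `"none"` for ordinary (non-persistent) Laplacians.
#' @param max_points Guard on subset size for the exact Alpha builder.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(elements = c("C", "N", "O"),
                           site_types = c("mutation", "binding"),
                           r_mut = 10, r_bind = 12,
                           grid0 = seq(0, 12, by = 0.25),
                           grid12 = seq(0, 12, by = 0.5),
                           dims = 0:2,
                           mode0 = c("mod", "euclidean"),
                           alpha_prune = FALSE,
                           persistence = c("step", "none"),
                           max_points = 250) {
  mode0 <- match.arg(mode0)
  persistence <- match.arg(persistence)
  stopifnot(all(dims %in% 0:2), length(elements) > 0,
            all(site_types %in% c("mutation", "binding")))
  structure(list(elements = elements, site_types = site_types,
                 r_mut = r_mut, r_bind = r_bind, grid0 = sort(grid0),
                 grid12 = sort(grid12), dims = sort(dims), mode0 = mode0,
                 alpha_prune = alpha_prune, persistence = persistence,
                 max_points = max_points),
            class = "feature_config")
}

stat_names <- function() {
  c("n_harmonic", "nh_min", "nh_max", "nh_mean", "nh_sd", "nh_sum",
    "nh_var", "nh_present")
}

block_names <- function(site, e1, e2, k, grid) {
  as.vector(t(outer(paste0(site, "_", e1, e2, "_k", k, "_t",
                           formatC(grid, format = "g")),
                    stat_names(), paste, sep = "_")))
}

# spectra statistics along one grid for one labeled point cloud
grid_block <- function(coords, groups, k, grid, p_step, source, mode,
                       prune) {
  n_stats <- length(stat_names())
  out <- numeric(length(grid) * n_stats)
  if (length(groups) >= 1) {
    cx <- if (source == "rips") {
      d <- euclid_cross(coords, coords)
      if (mode == "mod") d[outer(groups, groups, "==")] <- Inf
      diag(d) <- 0
      build_rips(d, max_dim = min(k + 1, 3), max_filtration = max(grid) +
                 p_step + 1e-9)
    } else {
      a <- build_alpha(coords, max_dim = 3,
                       max_filtration = max(grid) + p_step + 1e-9)
      if (prune) a <- prune_cross_only(a, groups) else a
    }
    for (i in seq_along(grid)) {
      t0 <- grid[i]
      t1 <- if (p_step > 0 && i < length(grid)) grid[i + 1] else t0
      L <- if (t1 > t0) {
        persistent_laplacian(snapshot(cx, t0), snapshot(cx, t1), k)
      } else {
        combinatorial_laplacian(snapshot(cx, t0), k)
      }
      sp <- spectrum(L, k = k, t = t0, p = t1 - t0)
      out[((i - 1) * n_stats + 1):(i * n_stats)] <- spectral_statistics(sp)
    }
  }
  out
}

#' Topological feature block of one structure
#'
#' For every configured (site type, element pair, dimension, grid value),
#' the harmonic and non-harmonic spectral statistics of the (persistent)
#' Laplacian of the corresponding labeled point cloud: dimension 0 from a
#' Vietoris-Rips filtration under the configured distance mode, dimensions
#' 1-2 from the Alpha filtration of the same cloud. Empty subsets yield
#' all-zero sub-blocks so the schema is fixed.
#'
#' @param s A `Structure` with a P1/P2 partition.
#' @param mut A `MutationSpec` locating the mutation site.
#' @param config A [feature_config()].
#' @return Named numeric vector; the names are the feature schema.
#' @export
filtration_features <- function(s, mut, config = feature_config()) {
  subsets <- site_subsets(s, mut, config$r_mut, config$r_bind)
  p_step0 <- if (config$persistence == "step" && length(config$grid0) > 1) {
    min(diff(config$grid0))
  } else 0
  p_step12 <- if (config$persistence == "step" &&
                  length(config$grid12) > 1) min(diff(config$grid12)) else 0

  pairs <- expand.grid(e1 = config$elements, e2 = config$elements,
                       stringsAsFactors = FALSE)
  out <- numeric(0)
  nms <- character(0)
  for (site in config$site_types) {
    if (site == "mutation") {
      base_a <- subsets$a_m
      base_b <- setdiff(subsets$a_mn, subsets$a_m)
      lab <- c("site", "nbhd")
    } else {
      base_a <- subsets$a_p1
      base_b <- subsets$a_p2
      lab <- c("P1", "P2")
    }
    for (j in seq_len(nrow(pairs))) {
      e1 <- pairs$e1[j]; e2 <- pairs$e2[j]
      ia <- filter_by_element(s, base_a, e1)
      ib <- filter_by_element(s, base_b, e2)
      cloud_idx <- c(ia, ib)
      groups <- rep(lab, c(length(ia), length(ib)))
      empty <- length(ia) == 0 || length(ib) == 0
      if (length(cloud_idx) > config$max_points) {
        stop("subset ", site, " ", e1, "-", e2, " has ", length(cloud_idx),
             " atoms, above max_points = ", config$max_points)
      }
      coords <- structure_coords(s, cloud_idx)
      for (k in config$dims) {
        grid <- if (k == 0) config$grid0 else config$grid12
        vals <- if (empty) {
          numeric(length(grid) * length(stat_names()))
        } else if (k == 0) {
          grid_block(coords, groups, 0, grid, p_step0, "rips",
                     config$mode0, FALSE)
        } else {
          grid_block(coords, groups, k, grid, p_step12, "alpha",
                     "euclidean", config$alpha_prune)
        }
        out <- c(out, vals)
        nms <- c(nms, block_names(site, e1, e2, k, grid))
      }
    }
  }
  names(out) <- nms
  out
}

#' Mutant structure by side-chain truncation
#'
#' Default fallback when no modelled mutant structure is supplied: the
#' mutated residue keeps its backbone atoms (and CB unless the mutant is
#' glycine) and is renamed; no side-chain rebuilding or repacking is
#' attempted.
#'
#' @param s Wild-type `Structure`.
#' @param mut A `MutationSpec`.
#' @return A `Structure` for the truncated mutant.
#' @export
build_mutant <- function(s, mut) {
  idx <- select_mutation_site(s, mut, on_mismatch = "warn")
  atoms <- s$atoms
  keep_names <- c(BACKBONE_ATOMS, if (mut$mut_aa != "G") "CB")
  drop <- idx[!(atoms$name[idx] %in% keep_names)]
  if (length(drop) > 0) atoms <- atoms[-drop, , drop = FALSE]
  sel <- atoms$chain == mut$chain & atoms$res_seq == mut$res_seq
  atoms$res_name[sel] <- AA3[match(mut$mut_aa, AA1)]
  new_structure(paste0(s$id, "_", format_mutation_code(mut)), atoms,
                s$partition)
}

#' Assemble the wild-type / mutant / difference feature vector
#'
#' Concatenates the wild-type block, the mutant block and their difference
#' (mutant minus wild-type, the explicit delta channel for a difference
#' quantity like ddG), plus an optional plug-in block for externally
#' computed embeddings.
#'
#' @param wt Wild-type `Structure`.
#' @param mut_s Mutant `Structure` (e.g. from [build_mutant()] or a modelled
#'   structure); must share the wild-type's partition scheme.
#' @param mut A `MutationSpec` resolvable in both structures.
#' @param config A [feature_config()].
#' @param plugin Optional named numeric vector appended unchanged (external
#'   per-residue embeddings; not computed by this package).
#' @return Named numeric `FeatureVector` with attribute `config_hash`.
#' @export
assemble_features <- function(wt, mut_s, mut, config = feature_config(),
                              plugin = NULL) {
  fw <- filtration_features(wt, mut, config)
  fm <- filtration_features(mut_s, mut, config)
  if (!identical(names(fw), names(fm))) {
    stop("wild-type and mutant feature schemas disagree")
  }
  out <- c(stats::setNames(fw, paste0("wt_", names(fw))),
           stats::setNames(fm, paste0("mut_", names(fm))),
           stats::setNames(fm - fw, paste0("diff_", names(fw))))
  if (!is.null(plugin)) {
    if (is.null(names(plugin)) || any(!nzchar(names(plugin)))) {
      stop("plugin features must be named")
    }
    out <- c(out, stats::setNames(plugin, paste0("plugin_", names(plugin))))
  }
  if (any(!is.finite(out))) stop("non-finite feature value")
  attr(out, "config_hash") <- rlang::hash(unclass(config))
  out
}
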