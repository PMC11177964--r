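# Synthetic structures and datasets: toy two-chain complexes with
# controlled interface geometry, per-residue perturbations, and mutation
# datasets whose ddG is a known function of the features. All generators
# are pure functions of (configuration, seed).

helix_backbone <- function(n_res, chain, aa_offset = 0) {
  # idealized alpha-helical geometry: 2.3 A radius, 1.5 A rise and 100
  # degrees of twist per residue; backbone + CB only
  i <- seq_len(n_res) - 1
  theta <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  radial <- cbind(cos(theta), sin(theta), 0)
  axis_dir <- c(0, 0, 1)
  step <- rbind(ca[2, ] - ca[1, ], diff(ca))
  n_at <- ca - 0.45 * step + 0.35 * radial
  c_at <- ca + 0.55 * step + 0.35 * radial
  o_at <- c_at + 1.23 * radial
  cb <- ca + 1.53 * radial + 0.3 * matrix(axis_dir, n_res, 3, byrow = TRUE)

  aa_idx <- ((i + aa_offset) %% 20) + 1
  res_name <- AA3[aa_idx]
  rows <- list()
  for (r in seq_len(n_res)) {
    names_r <- c("N", "CA", "C", "O", if (res_name[r] != "GLY") "CB")
    coords_r <- rbind(n_at[r, ], ca[r, ], c_at[r, ], o_at[r, ],
                      if (res_name[r] != "GLY") cb[r, ])
    rows[[r]] <- data.frame(
      element = substr(names_r, 1, 1),
      x = coords_r[, 1], y = coords_r[, 2], z = coords_r[, 3],
      chain = chain, res_seq = as.character(r), res_name = res_name[r],
      name = names_r, b_factor = 0,
      is_backbone = names_r %in% BACKBONE_ATOMS,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a toy two-chain helical complex
#'
#' Two idealized helices (chains A = P1 and B = P2) side by side, with a
#' requested number of chain-B residues displaced into contact (closest
#' heavy-atom distance about 4 angstrom) with chain A. Synthetic B-factors
#' increase quadratically toward the chain termini, mimicking terminal
#' flexibility. Deterministic for a given configuration and seed.
#'
#' @param residues_per_chain At least 3.
#' @param interface_contacts Number of chain-B residues brought within 5
#'   angstrom of chain A (0 keeps the chains fully separated).
#' @param noise_sigma Isotropic Gaussian coordinate noise, angstrom.
#' @param seed Integer seed.
#' @param id Structure identifier.
#' @return A `Structure` with partition A = P1, B = P2.
#' @export
make_toy_dimer <- function(residues_per_chain = 30, interface_contacts = 4,
                           noise_sigma = 0, seed = 1, id = "TOY") {
  if (residues_per_chain < 3) stop("residues_per_chain must be >= 3")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (interface_contacts < 0 ||
      interface_contacts > residues_per_chain - 2) {
    stop("infeasible contact count: need 0 <= contacts <= ",
         residues_per_chain - 2)
  }
  a <- helix_backbone(residues_per_chain, "A", aa_offset = 0)
  b <- helix_backbone(residues_per_chain, "B", aa_offset = 7)
  b$x <- b$x + 16   # well outside contact range before displacement

  if (interface_contacts > 0) {
    picks <- round(seq(2, residues_per_chain - 1,
                       length.out = interface_contacts))
    picks <- unique(picks)
    if (length(picks) < interface_contacts) {
      stop("infeasible contact count for this chain length")
    }
    for (r in picks) {
      bi <- b$res_seq == as.character(r)
      bm <- as.matrix(b[bi, c("x", "y", "z")])
      am <- as.matrix(a[, c("x", "y", "z")])
      dm <- euclid_cross(bm, am)
      w <- which(dm == min(dm), arr.ind = TRUE)[1, ]
      # move the residue along the closest-pair direction so the minimum
      # heavy-atom distance becomes exactly 4 angstrom
      dirv <- am[w[2], ] - bm[w[1], ]
      dirv <- dirv / sqrt(sum(dirv^2))
      shift <- (min(dm) - 4.0) * dirv
      b[bi, c("x", "y", "z")] <- sweep(bm, 2, shift, "+")
    }
  }
  atoms <- rbind(a, b)

  mid <- (residues_per_chain + 1) / 2
  resno <- as.numeric(atoms$res_seq)
  atoms$b_factor <- 10 + 40 * ((resno - mid) / mid)^2

  if (noise_sigma > 0) {
    set.seed(seed)
    atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
      matrix(stats::rnorm(3 * nrow(atoms), 0, noise_sigma), ncol = 3)
  }
  s <- new_structure(id, atoms, c(A = "P1", B = "P2"))

  if (interface_contacts == 0) {
    p1 <- which(s$partition[s$atoms$chain] == "P1")
    p2 <- which(s$partition[s$atoms$chain] == "P2")
    stopifnot(min(euclid_cross(structure_coords(s, p1),
                               structure_coords(s, p2))) > 5)
  }
  s
}

#' Random proper rotation matrix
#'
#' @param seed Optional integer seed.
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Displace residues by a prescribed per-residue profile
#'
#' Each residue's atoms move together along a random direction, scaled to
#' the residue's profile value (angstrom); an optional rigid motion is
#' composed on top. Emulates localized model error in flexible regions.
#'
#' @param s A `Structure`.
#' @param profile Non-negative numeric vector, one value per residue in
#'   structure order (chain then residue), or a single value recycled.
#' @param seed Integer seed for the displacement directions.
#' @param rigid `NULL` (none), `TRUE` (random rigid motion), or a list with
#'   `rotation` and `translation`.
#' @return The perturbed `Structure`.
#' @export
perturb_structure <- function(s, profile, seed = 1, rigid = NULL) {
  if (any(profile < 0) || any(!is.finite(profile))) {
    stop("displacement profile must be finite and non-negative")
  }
  key <- paste(s$atoms$chain, s$atoms$res_seq)
  res_keys <- unique(key)
  profile <- rep_len(profile, length(res_keys))
  set.seed(seed)
  dirs <- matrix(stats::rnorm(3 * length(res_keys)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  disp <- dirs * profile
  atoms <- s$atoms
  idx <- match(key, res_keys)
  atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] + disp[idx, ]
  if (isTRUE(rigid)) {
    rigid <- list(rotation = random_rotation(),
                  translation = stats::rnorm(3, 0, 10))
  }
  if (!is.null(rigid)) {
    atoms[, c("x", "y", "z")] <-
      apply_rigid(as.matrix(atoms[, c("x", "y", "z")]), rigid$rotation,
                  rigid$translation)
  }
  new_structure(s$id, atoms, s$partition)
}

#' Synthetic mutation dataset with a known effect model
#'
#' Features are standard normal; ddG is a sparse linear function of the
#' first `n_active` features plus Gaussian noise, so that a learner's
#' ability to recover the generative model can be measured exactly.
#' Optionally each record gets a reciprocal partner with negated features
#' and exactly negated ddG, mirroring forward/reverse mutations.
#'
#' @param n Number of base records (at least 20).
#' @param seed Integer seed.
#' @param d Number of features.
#' @param beta Active coefficients (kcal/mol per unit feature); their
#'   length sets `n_active`.
#' @param noise_sigma Noise standard deviation, kcal/mol.
#' @param n_complexes Number of synthetic complexes records are assigned
#'   to (round robin), for grouped cross-validation.
#' @param reciprocal Add mirrored reverse-mutation records.
#' @return List: `records` (data.frame with `complex_id`, `mutation`,
#'   `ddg`, `pair_id`), `features` (matrix), `beta`, `noise_sigma`.
#' @export
synth_mutation_dataset <- function(n = 500, seed = 42, d = 20,
                                   beta = c(1.6, -1.3, 1.1, 0.9, -0.7),
                                   noise_sigma = 0.3, n_complexes = 20,
                                   reciprocal = FALSE) {
  if (n < 20) stop("n must be at least 20")
  if (d < length(beta)) stop("d must be at least length(beta)")
  set.seed(seed)
  X <- matrix(stats::rnorm(n * d), nrow = n,
              dimnames = list(NULL, sprintf("feat_%02d", seq_len(d))))
  y <- as.numeric(X[, seq_along(beta), drop = FALSE] %*% beta +
                  stats::rnorm(n, 0, noise_sigma))

  pos <- sample(5:300, n, replace = TRUE)
  wt <- sample(AA1, n, replace = TRUE)
  mut <- vapply(wt, function(a) sample(setdiff(AA1, a), 1), "")
  records <- data.frame(
    complex_id = sprintf("SYN%03d", (seq_len(n) - 1) %% n_complexes + 1),
    mutation = paste0(wt, "A", pos, mut),
    ddg = y, pair_id = seq_len(n),
    stringsAsFactors = FALSE)
  if (reciprocal) {
    rev_rec <- records
    rev_rec$mutation <- paste0(mut, "A", pos, wt)
    rev_rec$ddg <- -records$ddg
    records <- rbind(records, rev_rec)
    X <- rbind(X, -X)
  }
  list(records = records, features = X, beta = beta,
       noise_sigma = noise_sigma)
}

#' Write a complete synthetic fixture set
#'
#' Generates a toy dimer, a perturbed "predicted" copy, a confidence
#' summary stub and a manifest CSV wiring them together - the offline
#' counterpart of a reference/predicted/confidence evaluation batch.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_complexes Number of toy complexes to write.
#' @return Invisibly, the manifest path.
#' @export
make_fixtures <- function(out_dir, seed = 1, n_complexes = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_len(n_complexes)) {
    id <- sprintf("TOY%02d", i)
    ref <- make_toy_dimer(residues_per_chain = 20, interface_contacts = 3,
                          seed = seed + i, id = id)
    profile <- 0.02 * tapply(ref$atoms$b_factor,
                             paste(ref$atoms$chain, ref$atoms$res_seq),
                             mean)
    key <- unique(paste(ref$atoms$chain, ref$atoms$res_seq))
    prd <- perturb_structure(ref, as.numeric(profile[key]), seed = seed + i,
                             rigid = TRUE)
    ref_path <- file.path(out_dir, paste0(id, "_ref.pdb"))
    prd_path <- file.path(out_dir, paste0(id, "_pred.pdb"))
    conf_path <- file.path(out_dir, paste0(id, "_confidence.json"))
    write_structure(ref, ref_path)
    write_structure(prd, prd_path)
    set.seed(seed + i)
    jsonlite::write_json(list(iptm = round(stats::runif(1, 0.5, 0.95), 2),
                              ptm = round(stats::runif(1, 0.5, 0.95), 2)),
                         conf_path, auto_unbox = TRUE)
    rows[[i]] <- data.frame(complex_id = id, reference = ref_path,
                            predicted = prd_path, confidence = conf_path,
                            stringsAsFactors = FALSE)
  }
  manifest <- file.path(out_dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
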