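# Predicted-vs-reference complex evaluation: chain mapping, Kabsch
# superposition, global and per-residue backbone RMSD, B-factor joins and
# confidence-score summaries.

three_to_one <- function(res_name) {
  out <- AA1[match(res_name, AA3)]
  out[is.na(out)] <- "X"
  out
}

residues_of <- function(s, chain) {
  a <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  first <- !duplicated(a$res_seq)
  data.frame(res_seq = a$res_seq[first], res_name = a$res_name[first],
             stringsAsFactors = FALSE)
}

chain_sequence <- function(s, chain) {
  paste(three_to_one(residues_of(s, chain)$res_name), collapse = "")
}

# residue index pairs matched by global sequence alignment
aligned_pairs <- function(seq1, seq2) {
  if (identical(seq1, seq2)) {
    n <- nchar(seq1)
    return(cbind(seq_len(n), seq_len(n)))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq1), Biostrings::AAString(seq2),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  i <- 0L; j <- 0L
  out <- matrix(0L, nrow = 0, ncol = 2)
  pairs <- vector("list", length(p))
  for (pos in seq_along(p)) {
    if (p[pos] != "-") i <- i + 1L
    if (s[pos] != "-") j <- j + 1L
    if (p[pos] != "-" && s[pos] != "-") pairs[[pos]] <- c(i, j)
  }
  do.call(rbind, pairs[!vapply(pairs, is.null, TRUE)])
}

chain_identity <- function(seq1, seq2) {
  if (identical(seq1, seq2)) return(100)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq1), Biostrings::AAString(seq2),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(pa)
}

#' Map predicted chains onto reference chains
#'
#' Builds a bijection from predicted to reference chain identifiers by
#' greedily pairing the highest global-alignment sequence identities. When
#' several assignments are essentially tied (homomeric complexes), all tied
#' bijections are compared by whole-complex C-alpha superposition RMSD and
#' the best one is kept.
#'
#' @param predicted,reference `Structure` objects.
#' @param min_identity Lowest acceptable percent identity for a pair
#'   (default 30).
#' @return Named character vector: predicted chain -> reference chain.
#' @export
map_chains <- function(predicted, reference, min_identity = 30) {
  pc <- unique(predicted$atoms$chain)
  rc <- unique(reference$atoms$chain)
  ps <- vapply(pc, function(ch) chain_sequence(predicted, ch), "")
  rs <- vapply(rc, function(ch) chain_sequence(reference, ch), "")
  idm <- outer(seq_along(pc), seq_along(rc),
               Vectorize(function(i, j) chain_identity(ps[i], rs[j])))

  greedy <- function(m) {
    map <- character(0)
    used_p <- logical(length(pc)); used_r <- logical(length(rc))
    repeat {
      m2 <- m
      m2[used_p, ] <- -Inf; m2[, used_r] <- -Inf
      if (all(!is.finite(m2))) break
      w <- which(m2 == max(m2), arr.ind = TRUE)[1, , drop = TRUE]
      map[pc[w[1]]] <- rc[w[2]]
      used_p[w[1]] <- TRUE; used_r[w[2]] <- TRUE
      if (all(used_p) || all(used_r)) break
    }
    map
  }
  map <- greedy(idm)

  unmapped <- setdiff(rc, map)
  if (length(unmapped) > 0) {
    best <- vapply(unmapped, function(ch) max(idm[, match(ch, rc)]), 0)
    stop("no predicted chain maps to reference chain(s): ",
         paste0(unmapped, " (best identity ", round(best, 1), "%)",
                collapse = ", "))
  }
  low <- idm[cbind(match(names(map), pc), match(map, rc))] < min_identity
  if (any(low)) {
    stop("chain mapping below ", min_identity, "% identity for: ",
         paste(names(map)[low], collapse = ", "))
  }

  # resolve homomer ambiguity: enumerate tied bijections by RMSD
  tied <- any(apply(idm, 2, function(col) sum(col >= max(col) - 0.5) > 1))
  if (tied && length(pc) <= 4) {
    perms <- all_bijections(pc, rc)
    ok <- Filter(function(mp) {
      all(idm[cbind(match(names(mp), pc), match(mp, rc))] >= min_identity)
    }, perms)
    if (length(ok) > 1) {
      rmsds <- vapply(ok, function(mp) {
        tryCatch(superpose_structures(predicted, reference,
                                      chain_map = mp)$rmsd,
                 error = function(e) Inf)
      }, 0)
      map <- ok[[order(rmsds, vapply(ok, paste, "", collapse = ""))[1]]]
    }
  }
  map
}

all_bijections <- function(pc, rc) {
  k <- min(length(pc), length(rc))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(rest) c(v[i], rest))
    }), recursive = FALSE)
  }
  out <- list()
  for (p in perms(rc)) {
    out[[length(out) + 1]] <- stats::setNames(p[seq_len(k)], pc[seq_len(k)])
  }
  out
}

#' Optimal rigid superposition of paired coordinate sets
#'
#' Least-squares (Kabsch) alignment of `moving` onto `fixed`: proper
#' rotation plus translation minimizing the RMSD.
#'
#' @param moving,fixed Numeric matrices, one 3-D point per row, equal row
#'   counts (at least 3 non-collinear points).
#' @return An `AlignmentResult` list: `rotation` (3x3, det +1),
#'   `translation` (length 3, angstrom), `rmsd` (angstrom), `moved`
#'   (transformed coordinates).
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) stop("paired sets differ in size")
  if (nrow(moving) < 3) stop("need at least 3 paired points")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  X <- sweep(moving, 2, cm); Y <- sweep(fixed, 2, cf)
  if (svd_rank(X) < 2 || svd_rank(Y) < 2) {
    stop("degenerate (collinear) point set")
  }
  H <- crossprod(X, Y)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- X %*% t(R)
  moved <- sweep(moved, 2, cf, "+")
  structure(list(rotation = R, translation = as.numeric(cf - R %*% cm),
                 rmsd = sqrt(mean(rowSums((moved - fixed)^2))),
                 moved = moved),
            class = "AlignmentResult")
}

apply_rigid <- function(coords, rotation, translation) {
  sweep(coords %*% t(rotation), 2, translation, "+")
}

# matched residue tables for one chain pair
pair_residues <- function(predicted, reference, pchain, rchain) {
  rp <- residues_of(predicted, pchain)
  rr <- residues_of(reference, rchain)
  ap <- aligned_pairs(paste(three_to_one(rp$res_name), collapse = ""),
                      paste(three_to_one(rr$res_name), collapse = ""))
  data.frame(pchain = pchain, rchain = rchain,
             pres = rp$res_seq[ap[, 1]], rres = rr$res_seq[ap[, 2]],
             stringsAsFactors = FALSE)
}

#' Superpose a predicted complex onto its reference
#'
#' Pairs residues chain by chain through global sequence alignment, fits the
#' whole complex on the shared C-alpha atoms (or full backbone) by
#' [kabsch_superpose()], and reports the global RMSD together with the
#' per-residue backbone RMSD table.
#'
#' @param predicted,reference `Structure` objects.
#' @param chain_map Predicted -> reference chain map; computed by
#'   [map_chains()] when `NULL`.
#' @param fit_atoms `"CA"` (default) or `"backbone"`: atoms used for the
#'   global fit. Per-residue values always use the full backbone.
#' @return An `AlignmentResult` with `rotation`, `translation`, `rmsd`,
#'   `per_residue` (data.frame: chain, res_seq, rmsd), `chain_map`,
#'   `n_skipped_residues`.
#' @export
superpose_structures <- function(predicted, reference, chain_map = NULL,
                                 fit_atoms = c("CA", "backbone")) {
  fit_atoms <- match.arg(fit_atoms)
  if (is.null(chain_map)) chain_map <- map_chains(predicted, reference)
  fit_names <- if (fit_atoms == "CA") "CA" else BACKBONE_ATOMS

  pairs <- do.call(rbind, lapply(names(chain_map), function(pc) {
    pair_residues(predicted, reference, pc, chain_map[[pc]])
  }))
  if (is.null(pairs) || nrow(pairs) == 0) stop("no paired residues")

  mv <- list(); fx <- list()
  pa <- predicted$atoms; ra <- reference$atoms
  for (i in seq_len(nrow(pairs))) {
    psel <- pa$chain == pairs$pchain[i] & pa$res_seq == pairs$pres[i] &
      pa$name %in% fit_names
    rsel <- ra$chain == pairs$rchain[i] & ra$res_seq == pairs$rres[i] &
      ra$name %in% fit_names
    common <- intersect(pa$name[psel], ra$name[rsel])
    if (length(common) == 0) next
    mv[[length(mv) + 1]] <-
      as.matrix(pa[psel, ][match(common, pa$name[psel]), c("x", "y", "z")])
    fx[[length(fx) + 1]] <-
      as.matrix(ra[rsel, ][match(common, ra$name[rsel]), c("x", "y", "z")])
  }
  fit <- kabsch_superpose(do.call(rbind, mv), do.call(rbind, fx))

  pr <- per_residue_rmsd(predicted, reference, chain_map,
                         list(rotation = fit$rotation,
                              translation = fit$translation),
                         residue_pairs = pairs)
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = fit$rmsd, per_residue = pr$table,
                 chain_map = chain_map,
                 n_skipped_residues = pr$n_skipped),
            class = "AlignmentResult")
}

#' Per-residue backbone RMSD under a given global superposition
#'
#' For every residue pair matched by the chain map and sequence alignment,
#' the quadratic-mean deviation over the backbone atoms (N, CA, C, O)
#' present in both structures, after applying the global rigid transform to
#' the predicted coordinates. Residues sharing no backbone atom are skipped
#' and counted.
#'
#' @param predicted,reference `Structure` objects.
#' @param chain_map Predicted -> reference chain map.
#' @param alignment List with `rotation` and `translation` (e.g. an
#'   `AlignmentResult`).
#' @param residue_pairs Internal: precomputed residue pairing.
#' @return List: `table` (data.frame chain, res_seq, res_name, rmsd - on
#'   reference numbering) and `n_skipped`.
#' @export
per_residue_rmsd <- function(predicted, reference, chain_map, alignment,
                             residue_pairs = NULL) {
  if (is.null(residue_pairs)) {
    residue_pairs <- do.call(rbind, lapply(names(chain_map), function(pc) {
      pair_residues(predicted, reference, pc, chain_map[[pc]])
    }))
  }
  pa <- predicted$atoms; ra <- reference$atoms
  n_skipped <- 0L
  rows <- vector("list", nrow(residue_pairs))
  for (i in seq_len(nrow(residue_pairs))) {
    psel <- pa$chain == residue_pairs$pchain[i] &
      pa$res_seq == residue_pairs$pres[i] & pa$is_backbone
    rsel <- ra$chain == residue_pairs$rchain[i] &
      ra$res_seq == residue_pairs$rres[i] & ra$is_backbone
    common <- intersect(pa$name[psel], ra$name[rsel])
    if (length(common) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    pm <- as.matrix(pa[psel, ][match(common, pa$name[psel]),
                               c("x", "y", "z")])
    rm <- as.matrix(ra[rsel, ][match(common, ra$name[rsel]),
                               c("x", "y", "z")])
    pm <- apply_rigid(pm, alignment$rotation, alignment$translation)
    rows[[i]] <- data.frame(
      chain = residue_pairs$rchain[i], res_seq = residue_pairs$rres[i],
      res_name = ra$res_name[rsel][1],
      rmsd = sqrt(mean(rowSums((pm - rm)^2))),
      stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
       n_skipped = n_skipped)
}

#' Join per-residue RMSD with reference B-factors
#'
#' Produces the residue-level table relating model error to crystallographic
#' flexibility: mean backbone B-factor, backbone RMSD and amino-acid type
#' per residue.
#'
#' @param reference `Structure` carrying B-factors.
#' @param per_residue Per-residue RMSD table (from
#'   [superpose_structures()]'s `per_residue` or [per_residue_rmsd()]).
#' @return data.frame: `complex_id`, `chain`, `res_seq`, `b_factor`,
#'   `rmsd`, `aa`. Structures whose B-factors are all zero are flagged with
#'   a warning.
#' @export
bfactor_rmsd_table <- function(reference, per_residue) {
  ra <- reference$atoms
  if (all(ra$b_factor == 0)) {
    warning("reference ", reference$id, " has all-zero B-factors")
  }
  b <- mapply(function(ch, rs) {
    sel <- ra$chain == ch & ra$res_seq == rs & ra$is_backbone
    if (!any(sel)) sel <- ra$chain == ch & ra$res_seq == rs
    mean(ra$b_factor[sel])
  }, per_residue$chain, per_residue$res_seq)
  data.frame(complex_id = reference$id, chain = per_residue$chain,
             res_seq = per_residue$res_seq, b_factor = as.numeric(b),
             rmsd = per_residue$rmsd,
             aa = three_to_one(per_residue$res_name),
             stringsAsFactors = FALSE)
}

#' Evaluate one predicted complex against its reference
#'
#' @param predicted,reference `Structure` objects.
#' @param confidence Optional list with `iptm`/`ptm` (see
#'   [parse_confidence()]).
#' @param mean_abs_error Optional mean absolute ddG prediction error
#'   (kcal/mol) to carry along.
#' @return One-row data.frame of class `ComplexEvaluation` plus attributes
#'   `alignment` and `bfactor_table`.
#' @export
evaluate_complex <- function(predicted, reference, confidence = NULL,
                             mean_abs_error = NA_real_) {
  al <- superpose_structures(predicted, reference)
  out <- data.frame(complex_id = reference$id, rmsd = al$rmsd,
                    iptm = if (is.null(confidence)) NA_real_ else
                      confidence$iptm,
                    ptm = if (is.null(confidence)) NA_real_ else
                      confidence$ptm,
                    mean_abs_error = mean_abs_error,
                    stringsAsFactors = FALSE)
  attr(out, "alignment") <- al
  attr(out, "bfactor_table") <- bfactor_rmsd_table(reference, al$per_residue)
  class(out) <- c("ComplexEvaluation", "data.frame")
  out
}

#' Summarize and rank a batch of complex evaluations
#'
#' Means of RMSD/ipTM/pTM, the fractions in the standard confidence bands
#' (ipTM at least 0.8: highly confident; ipTM below 0.6: likely incorrect;
#' pTM at least 0.5: acceptable overall fold), the top-N lists by highest
#' RMSD and by lowest ipTM, and their intersection (complexes poor by both
#' measures). Ranking is stable: ties break lexicographically on complex
#' id.
#'
#' @param evals data.frame with columns `complex_id`, `rmsd`, `iptm`,
#'   `ptm`.
#' @param top_n Length of the ranking lists (default 40).
#' @param thresholds List with `iptm_high` (0.8), `iptm_low` (0.6),
#'   `ptm_ok` (0.5), `rmsd_outlier` (4 angstrom).
#' @return List: `summary` (means), `fractions`, `top_rmsd`, `low_iptm`,
#'   `poor_both`, `n_rmsd_outliers`.
#' @export
summarize_and_rank <- function(evals, top_n = 40,
                               thresholds = list(iptm_high = 0.8,
                                                 iptm_low = 0.6,
                                                 ptm_ok = 0.5,
                                                 rmsd_outlier = 4)) {
  if (nrow(evals) == 0) stop("empty evaluation set")
  top_rmsd <- evals$complex_id[order(-evals$rmsd, evals$complex_id)]
  low_iptm <- evals$complex_id[order(evals$iptm, evals$complex_id)]
  top_rmsd <- utils::head(top_rmsd, top_n)
  low_iptm <- utils::head(low_iptm, top_n)
  list(
    summary = c(mean_rmsd = mean(evals$rmsd), mean_iptm = mean(evals$iptm),
                mean_ptm = mean(evals$ptm)),
    fractions = c(
      iptm_high = mean(evals$iptm >= thresholds$iptm_high),
      iptm_low = mean(evals$iptm < thresholds$iptm_low),
      ptm_ok = mean(evals$ptm >= thresholds$ptm_ok)),
    n_rmsd_outliers = sum(evals$rmsd > thresholds$rmsd_outlier),
    top_rmsd = top_rmsd,
    low_iptm = low_iptm,
    poor_both = sort(intersect(top_rmsd, low_iptm)))
}

#' Batch evaluation driven by a manifest table
#'
#' The manifest CSV must have columns `complex_id`, `reference`,
#' `predicted` and optionally `confidence` (paths). Writes a per-complex
#' CSV, a per-residue CSV and a plain-text summary into `out_dir`.
#'
#' @param manifest Path to the manifest CSV.
#' @param out_dir Output directory (created if needed).
#' @param top_n Passed to [summarize_and_rank()].
#' @return Invisibly, a list with `evaluations`, `per_residue`, `summary`.
#' @export
evaluate_manifest <- function(manifest, out_dir, top_n = 40) {
  m <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  needed <- c("complex_id", "reference", "predicted")
  if (!all(needed %in% names(m))) {
    stop("manifest needs columns: ", paste(needed, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  evals <- list(); perres <- list()
  for (i in seq_len(nrow(m))) {
    ref <- parse_structure(m$reference[i], id = m$complex_id[i])
    prd <- parse_structure(m$predicted[i], id = m$complex_id[i])
    conf <- if ("confidence" %in% names(m) && nzchar(m$confidence[i])) {
      parse_confidence(m$confidence[i])
    } else NULL
    ev <- evaluate_complex(prd, ref, conf)
    evals[[i]] <- as.data.frame(ev)
    perres[[i]] <- attr(ev, "bfactor_table")
  }
  evals <- do.call(rbind, evals)
  perres <- do.call(rbind, perres)
  sm <- summarize_and_rank(evals, top_n = top_n)
  utils::write.csv(evals, file.path(out_dir, "complex_evaluations.csv"),
                   row.names = FALSE)
  utils::write.csv(perres, file.path(out_dir, "per_residue_rmsd.csv"),
                   row.names = FALSE)
  writeLines(c(
    sprintf("complexes evaluated: %d", nrow(evals)),
    sprintf("mean RMSD: %.3f A", sm$summary["mean_rmsd"]),
    sprintf("mean ipTM: %.3f  mean pTM: %.3f", sm$summary["mean_iptm"],
            sm$summary["mean_ptm"]),
    sprintf("fraction ipTM >= 0.8: %.3f", sm$fractions["iptm_high"]),
    sprintf("fraction ipTM < 0.6: %.3f", sm$fractions["iptm_low"]),
    sprintf("fraction pTM >= 0.5: %.3f", sm$fractions["ptm_ok"]),
    sprintf("RMSD outliers (> 4 A): %d", sm$n_rmsd_outliers),
    paste("poor in both rankings:", paste(sm$poor_both, collapse = " "))),
    file.path(out_dir, "summary.txt"))
  invisible(list(evaluations = evals, per_residue = perres, summary = sm))
}
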