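# Element/site-specific atom subsets and the modified distance matrix.
#
# Atom sets are integer row indices into structure$atoms; they compose with
# ordinary set operations (intersect, union, setdiff).

structure_coords <- function(s, idx = NULL) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

euclid_cross <- function(a, b) {
  # |a_i - b_j| for row sets a (n x 3) and b (m x 3)
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Atoms of the mutated residue
#'
#' All heavy atoms of the residue named by a mutation specification (the
#' mutation-site set around which the mutation-centric point clouds are
#' built).
#'
#' @param s A `Structure`.
#' @param mut A `MutationSpec` from [parse_mutation_code()].
#' @param on_mismatch What to do when the residue's name disagrees with the
#'   mutation's wild-type letter: `"warn"` (default), `"error"` or `"ignore"`.
#' @return Integer atom indices into `s$atoms`.
#' @export
select_mutation_site <- function(s, mut,
                                 on_mismatch = c("warn", "error", "ignore")) {
  on_mismatch <- match.arg(on_mismatch)
  idx <- which(s$atoms$chain == mut$chain & s$atoms$res_seq == mut$res_seq)
  if (length(idx) == 0) {
    stop("residue ", mut$res_seq, " on chain ", mut$chain,
         " not found in structure ", s$id)
  }
  res_name <- s$atoms$res_name[idx[1]]
  expected <- AA3[match(mut$wt_aa, AA1)]
  if (!is.na(expected) && res_name != expected && on_mismatch != "ignore") {
    msg <- paste0("residue ", mut$chain, ":", mut$res_seq, " is ", res_name,
                  ", mutation code says ", expected)
    if (on_mismatch == "error") stop(msg) else warning(msg)
  }
  idx
}

#' Atoms within a cutoff of the mutation site
#'
#' The mutation neighborhood: atoms whose minimum Euclidean distance to any
#' mutation-site atom is at most `r`. The mutation-site atoms themselves are
#' always included.
#'
#' @inheritParams select_mutation_site
#' @param r Cutoff radius in angstrom; must be positive.
#' @return Integer atom indices.
#' @export
select_neighborhood <- function(s, mut, r) {
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r <= 0) {
    stop("cutoff r must be a positive number (angstrom)")
  }
  site <- select_mutation_site(s, mut, on_mismatch = "ignore")
  d <- euclid_cross(structure_coords(s), structure_coords(s, site))
  sort(unique(c(site, which(apply(d, 1, min) <= r))))
}

#' Interface atoms of one binding partner
#'
#' Atoms of the chosen partner lying within `r` of any atom of the other
#' partner, i.e. the partner's side of the binding site at resolution `r`.
#'
#' @param s A `Structure` with a two-partner partition.
#' @param partner `"P1"` or `"P2"`.
#' @param r Cutoff radius in angstrom.
#' @return Integer atom indices, all on chains of the chosen partner.
#' @export
select_binding_site <- function(s, partner = c("P1", "P2"), r) {
  partner <- match.arg(partner)
  if (is.null(s$partition)) stop("structure has no P1/P2 partition")
  side <- s$partition[s$atoms$chain]
  if (!any(side == "P1") || !any(side == "P2")) {
    stop("both partners must be non-empty to define a binding site")
  }
  if (!is.finite(r)) return(which(side == partner))
  if (r <= 0) stop("cutoff r must be positive (angstrom)")
  own <- which(side == partner)
  other <- which(side != partner)
  d <- euclid_cross(structure_coords(s, own), structure_coords(s, other))
  own[apply(d, 1, min) <= r]
}

#' Restrict an atom set to given chemical elements
#'
#' @param s A `Structure`.
#' @param atoms Integer atom indices.
#' @param elements Character vector of element symbols, e.g. `c("C")` or
#'   `c("N", "O")`.
#' @return The subset of `atoms` whose element matches. May be empty.
#' @export
filter_by_element <- function(s, atoms, elements) {
  if (length(elements) == 0) stop("elements must be non-empty")
  atoms[s$atoms$element[atoms] %in% toupper(elements)]
}

#' All four site-specific subsets at once
#'
#' Convenience bundle: mutation-site atoms, their `r_mut` neighborhood, and
#' both partners' binding-site atoms at `r_bind`.
#'
#' @inheritParams select_mutation_site
#' @param r_mut Neighborhood cutoff (angstrom), default 10.
#' @param r_bind Binding-site cutoff (angstrom), default 12.
#' @return List with elements `a_m`, `a_mn`, `a_p1`, `a_p2`, `r_mut`,
#'   `r_bind`.
#' @export
site_subsets <- function(s, mut, r_mut = 10, r_bind = 12) {
  list(a_m = select_mutation_site(s, mut, on_mismatch = "ignore"),
       a_mn = select_neighborhood(s, mut, r_mut),
       a_p1 = select_binding_site(s, "P1", r_bind),
       a_p2 = select_binding_site(s, "P2", r_bind),
       r_mut = r_mut, r_bind = r_bind)
}

#' Pairwise distance matrix, Euclidean or cross-group modified
#'
#' In `"euclidean"` mode, plain Euclidean distances. In `"mod"` mode the
#' modified distance assigns `+Inf` to every pair of atoms belonging to the
#' same group, so that only cross-group pairs carry finite distances and the
#' topology built on the matrix reflects exclusively cross-group
#' interactions.
#'
#' @param s A `Structure`.
#' @param set_a,set_b Integer atom indices (rows and columns). `set_b`
#'   defaults to `set_a` (square matrix).
#' @param mode `"euclidean"` or `"mod"`.
#' @param grouping For `"mod"` mode: either `NULL` to use the structure's
#'   P1/P2 chain partition, or a character vector of group labels indexed by
#'   atom index (i.e. `grouping[i]` labels atom `i`).
#' @return A `DistanceMatrix` list: `entries` (angstrom, possibly `Inf`),
#'   `row_atoms`, `col_atoms`, `mode`.
#' @export
pairwise_distances <- function(s, set_a, set_b = set_a,
                               mode = c("euclidean", "mod"),
                               grouping = NULL) {
  mode <- match.arg(mode)
  d <- euclid_cross(structure_coords(s, set_a), structure_coords(s, set_b))
  if (mode == "mod") {
    if (is.null(grouping)) {
      if (is.null(s$partition)) {
        stop("mod mode needs a grouping (or a partitioned structure)")
      }
      grouping <- s$partition[s$atoms$chain]
    }
    ga <- grouping[set_a]
    gb <- grouping[set_b]
    if (any(is.na(ga)) || any(is.na(gb))) {
      stop("unlabeled atom(s) in mod mode")
    }
    d[outer(ga, gb, "==")] <- Inf
  }
  structure(list(entries = d, row_atoms = set_a, col_atoms = set_b,
                 mode = mode), class = "DistanceMatrix")
}
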