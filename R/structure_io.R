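# Structure, mutation and affinity-table I/O.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")
WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")
AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA3 <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE", "LYS", "LEU",
         "MET", "ASN", "PRO", "GLN", "ARG", "SER", "THR", "VAL", "TRP", "TYR")

## Gas constant in kcal/(mol K), SKEMPI convention.
GAS_CONSTANT_KCAL <- 1.9872e-3

#' Construct a two-partner protein complex structure
#'
#' A `Structure` is an atom table plus a partition of its chains into the two
#' binding partners P1 and P2. All topological subsets and interface
#' definitions are taken relative to this partition.
#'
#' @param id Identifier (e.g. a PDB code).
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`, `chain`,
#'   `res_seq` (author numbering as character, insertion code appended),
#'   `res_name`, `name`, `b_factor`, `is_backbone`.
#' @param partition Named character vector mapping every chain identifier to
#'   `"P1"` or `"P2"`. May be `NULL` for single-partner use (some operations
#'   then refuse to run).
#' @return An object of class `Structure`.
#' @export
new_structure <- function(id, atoms, partition = NULL) {
  required <- c("element", "x", "y", "z", "chain", "res_seq", "res_name",
                "name", "b_factor", "is_backbone")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$element))) stop("empty element symbol")
  if (any(atoms$b_factor < 0)) stop("negative B-factor")
  if (!is.null(partition)) {
    partition <- validate_partition(partition, unique(atoms$chain))
  }
  structure(list(id = id, atoms = atoms, partition = partition),
            class = "Structure")
}

validate_partition <- function(partition, chains) {
  if (!all(partition %in% c("P1", "P2"))) {
    stop("partition values must be 'P1' or 'P2'")
  }
  absent <- setdiff(chains, names(partition))
  if (length(absent) > 0) {
    stop("chain(s) missing from partition: ", paste(absent, collapse = ", "))
  }
  partition[chains]
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure", x$id, "-", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  if (!is.null(x$partition)) {
    for (side in c("P1", "P2")) {
      cat(" ", side, ":",
          paste(names(x$partition)[x$partition == side], collapse = " "), "\n")
    }
  }
  invisible(x)
}

infer_element <- function(atom_name) {
  # PDB atom names embed the element; strip digits/primes and leading digits
  nm <- gsub("[0-9']", "", trimws(atom_name))
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "SE", "NA", "CA"),
         # two-letter ions only occur as HETATM; for protein atoms first letter
         substr(nm, 1, 1), substr(nm, 1, 1))
}

#' Parse a protein complex structure from PDB or mmCIF
#'
#' Reads atom records, keeping element, coordinates, chain, author residue
#' numbering (with insertion codes), residue and atom names and B-factors.
#' Water and other HETATM records are excluded by default, hydrogens are
#' dropped (the topological subsets are defined over heavy atoms), and for
#' alternate conformations the highest-occupancy one is kept so that each
#' atom contributes a single point to the point cloud.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param partition Optional named character vector mapping chains to
#'   `"P1"`/`"P2"`.
#' @param keep_hetatm,keep_waters,keep_hydrogens Override the default filters.
#' @param id Identifier; defaults to the file base name.
#' @return A [new_structure()] object.
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                            partition = NULL, keep_hetatm = FALSE,
                            keep_waters = FALSE, keep_hydrogens = FALSE,
                            id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(withCallingHandlers(
    # keep all altlocs; the highest-occupancy conformer is selected below
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE,
                                         rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
    warning = function(w) {
      # known-noise bio3d messages on minimal files
      if (grepl("beta version|helix/sheet", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e)))
  at <- parsed$atom

  if (!keep_waters) at <- at[!(at$resid %in% WATER_RESIDUES), , drop = FALSE]
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms left after filtering in ", path)

  element <- trimws(as.character(at$elesy))
  no_elem <- is.na(element) | !nzchar(element)
  if (any(no_elem)) {
    warning(sum(no_elem), " atom(s) lack an element column; inferred from ",
            "atom names")
    element[no_elem] <- infer_element(at$elety[no_elem])
  }
  element <- toupper(element)
  if (!keep_hydrogens) {
    keep <- !(element %in% c("H", "D"))
    at <- at[keep, , drop = FALSE]
    element <- element[keep]
  }

  # altloc: keep the highest-occupancy conformer of each alternate group
  alt <- trimws(ifelse(is.na(at$alt), "", as.character(at$alt)))
  if (any(nzchar(alt))) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    key <- paste(at$chain, at$resno, trimws(ifelse(is.na(at$insert), "",
                 at$insert)), at$elety, sep = "|")
    ord <- order(key, -occ, alt)
    dup <- duplicated(key[ord])
    keep_idx <- sort(ord[!dup])
    at <- at[keep_idx, , drop = FALSE]
    element <- element[keep_idx]
  }

  insert <- trimws(ifelse(is.na(at$insert), "", as.character(at$insert)))
  atoms <- data.frame(
    element = element,
    x = at$x, y = at$y, z = at$z,
    chain = as.character(at$chain),
    res_seq = paste0(at$resno, insert),
    res_name = as.character(at$resid),
    name = trimws(as.character(at$elety)),
    b_factor = pmax(0, ifelse(is.na(at$b), 0, at$b)),
    is_backbone = trimws(as.character(at$elety)) %in% BACKBONE_ATOMS,
    stringsAsFactors = FALSE)

  if (is.null(id)) id <- sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path),
                             ignore.case = TRUE)
  new_structure(id, atoms, partition)
}

#' Write a structure to a PDB file
#'
#' Round-trip counterpart of [parse_structure()]; coordinates and B-factors
#' are written at PDB precision (1e-3 angstrom / 1e-2).
#'
#' @param s A `Structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  resno <- as.integer(sub("([0-9-]+).*", "\\1", a$res_seq))
  insert <- sub("^[0-9-]+", "", a$res_seq)
  insert[!nzchar(insert)] <- ""
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = resno, resid = a$res_name, chain = a$chain,
                   insert = insert, eleno = seq_len(nrow(a)), elety = a$name,
                   o = rep(1, nrow(a)), b = a$b_factor, elesy = a$element)
  invisible(path)
}

#' Parse an AF3-server style confidence summary
#'
#' Reads the structured-text (JSON) summary written alongside a predicted
#' complex and returns its interface and whole-complex predicted TM-scores.
#'
#' @param path Path to a JSON file containing `iptm` and `ptm` entries.
#' @return A list with elements `iptm` and `ptm`, both in `[0, 1]`.
#' @export
parse_confidence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::fromJSON(path)
  for (key in c("iptm", "ptm")) {
    if (is.null(x[[key]])) stop("confidence summary lacks key '", key, "'")
    v <- x[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("'", key, "' must be a single value in [0, 1], got: ",
           paste(v, collapse = ","))
    }
  }
  list(iptm = as.numeric(x$iptm), ptm = as.numeric(x$ptm))
}

#' Parse a SKEMPI-style mutation code
#'
#' Codes follow the `<wt><chain><position[icode]><mut>` convention, e.g.
#' `"TI38F"`: wild-type Thr, chain I, residue 38, mutant Phe.
#'
#' @param code Character scalar.
#' @return A `MutationSpec` list: `wt_aa`, `chain`, `res_seq`, `mut_aa`.
#' @export
parse_mutation_code <- function(code) {
  m <- regmatches(code,
    regexec("^([A-Z])([A-Za-z0-9])(-?[0-9]+[a-z]?)([A-Z])$", code))[[1]]
  if (length(m) != 5) stop("unrecognized mutation code: '", code, "'")
  wt <- m[2]; chain <- m[3]; res_seq <- m[4]; mut <- m[5]
  if (!(wt %in% AA1)) stop("wild-type letter '", wt, "' is not a canonical ",
                           "amino acid in '", code, "'")
  if (!(mut %in% AA1)) stop("mutant letter '", mut, "' is not a canonical ",
                            "amino acid in '", code, "'")
  if (wt == mut) stop("wild-type and mutant residues are identical in '",
                      code, "'")
  structure(list(wt_aa = wt, chain = chain, res_seq = res_seq, mut_aa = mut),
            class = "MutationSpec")
}

#' @rdname parse_mutation_code
#' @param mut A `MutationSpec`.
#' @export
format_mutation_code <- function(mut) {
  paste0(mut$wt_aa, mut$chain, mut$res_seq, mut$mut_aa)
}

#' Binding free energy change from wild-type and mutant affinities
#'
#' Uses the dissociation-constant convention `dG = RT ln Kd`, so
#' `ddG = RT ln(Kd_mut / Kd_wt)` with `R = 1.9872e-3` kcal/(mol K). Positive
#' values mean the mutation weakens binding.
#'
#' @param kd_wt,kd_mut Dissociation constants in molar; must be positive.
#' @param temperature Kelvin; must be positive.
#' @return ddG in kcal/mol (vectorized).
#' @export
ddg_from_affinities <- function(kd_wt, kd_mut, temperature) {
  if (any(!is.finite(kd_wt)) || any(kd_wt <= 0) ||
      any(!is.finite(kd_mut)) || any(kd_mut <= 0)) {
    stop("dissociation constants must be positive and finite")
  }
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperature must be positive (Kelvin)")
  }
  # difference of logs keeps the antisymmetry ddg(a,b) = -ddg(b,a) exact
  # in floating point
  GAS_CONSTANT_KCAL * temperature * (log(kd_mut) - log(kd_wt))
}

default_skempi_columns <- function() {
  list(pdb = "#Pdb", mutation = "Mutation(s)_cleaned",
       kd_wt = "Affinity_wt_parsed", kd_mut = "Affinity_mut_parsed",
       temperature = "Temperature")
}

parse_temperature <- function(x, default_temp) {
  out <- suppressWarnings(as.numeric(sub("^[^0-9]*([0-9]+\\.?[0-9]*).*$",
                                         "\\1", as.character(x))))
  bad <- !is.finite(out) | out <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable temperature; using ",
            default_temp, " K")
    out[bad] <- default_temp
  }
  out
}

#' Parse a SKEMPI-style mutation table into ddG records
#'
#' Reads a delimited table with one affinity measurement per row, keeps
#' single-mutation rows, derives ddG from the wild-type and mutant
#' dissociation constants via [ddg_from_affinities()], and averages duplicate
#' (complex, mutation) measurements. Rows with missing affinities are dropped
#' and counted. The complex field is expected in the `PDB_AB_C` dialect:
#' PDB code followed by the chain groups of the two partners.
#'
#' @param path Path to a CSV (`;` or `,` separated detected automatically).
#' @param col_map Named list overriding the default SKEMPI header names
#'   (`pdb`, `mutation`, `kd_wt`, `kd_mut`, `temperature`), or the path of a
#'   JSON/YAML file holding such a list.
#' @param default_temp Temperature (K) substituted when a row's value cannot
#'   be parsed.
#' @param average_duplicates Average ddG over repeated (complex, mutation)
#'   measurements (the default) instead of keeping every row.
#' @return A data.frame of class `ddg_records` with columns `complex_id`,
#'   `mutation`, `wt_aa`, `chain`, `res_seq`, `mut_aa`, `ddg` (kcal/mol),
#'   `temperature`, `kd_wt`, `kd_mut`, `chains_p1`, `chains_p2`, plus an
#'   attribute `n_dropped` counting removed rows.
#' @export
parse_skempi <- function(path, col_map = NULL, default_temp = 298,
                         average_duplicates = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- default_skempi_columns()
  if (is.character(col_map) && length(col_map) == 1 && file.exists(col_map)) {
    col_map <- jsonlite::fromJSON(col_map)
  }
  for (nm in names(col_map)) cols[[nm]] <- col_map[[nm]]

  header <- readLines(path, n = 1)
  sep <- if (lengths(regmatches(header, gregexpr(";", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) ";" else ","
  tab <- utils::read.csv(path, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE, comment.char = "")
  for (nm in names(cols)) {
    if (!(cols[[nm]] %in% names(tab))) {
      stop("table lacks column '", cols[[nm]], "' (", nm, ")")
    }
  }

  mutation <- trimws(tab[[cols$mutation]])
  single <- !grepl(",", mutation) & nzchar(mutation)
  kd_wt <- suppressWarnings(as.numeric(tab[[cols$kd_wt]]))
  kd_mut <- suppressWarnings(as.numeric(tab[[cols$kd_mut]]))
  has_kd <- is.finite(kd_wt) & kd_wt > 0 & is.finite(kd_mut) & kd_mut > 0
  keep <- single & has_kd
  n_dropped <- sum(single & !has_kd)
  if (n_dropped > 0) {
    message(n_dropped, " single-mutation row(s) dropped for missing or ",
            "non-positive affinities")
  }

  tab <- tab[keep, , drop = FALSE]
  mutation <- mutation[keep]
  kd_wt <- kd_wt[keep]; kd_mut <- kd_mut[keep]
  pdb_field <- strsplit(as.character(tab[[cols$pdb]]), "_")
  complex_id <- vapply(pdb_field, `[`, "", 1)
  chains_p1 <- vapply(pdb_field, function(p) if (length(p) >= 2) p[2] else "",
                      "")
  chains_p2 <- vapply(pdb_field, function(p) if (length(p) >= 3) p[3] else "",
                      "")
  temperature <- parse_temperature(tab[[cols$temperature]], default_temp)
  specs <- lapply(mutation, parse_mutation_code)
  rec <- data.frame(
    complex_id = complex_id,
    mutation = mutation,
    wt_aa = vapply(specs, `[[`, "", "wt_aa"),
    chain = vapply(specs, `[[`, "", "chain"),
    res_seq = vapply(specs, `[[`, "", "res_seq"),
    mut_aa = vapply(specs, `[[`, "", "mut_aa"),
    ddg = ddg_from_affinities(kd_wt, kd_mut, temperature),
    temperature = temperature,
    kd_wt = kd_wt, kd_mut = kd_mut,
    chains_p1 = chains_p1, chains_p2 = chains_p2,
    stringsAsFactors = FALSE)

  if (average_duplicates) {
    key <- paste(rec$complex_id, rec$mutation)
    if (anyDuplicated(key)) {
      first <- rec[!duplicated(key), , drop = FALSE]
      first$ddg <- tapply(rec$ddg, key, mean)[paste(first$complex_id,
                                                    first$mutation)]
      first$temperature <- tapply(rec$temperature, key,
                                  mean)[paste(first$complex_id,
                                              first$mutation)]
      rec <- first
    }
  }
  rownames(rec) <- NULL
  stopifnot(all(is.finite(rec$ddg)))
  attr(rec, "n_dropped") <- n_dropped
  class(rec) <- c("ddg_records", "data.frame")
  rec
}
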