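# Reading and modelling coordinate files.  Parsing of the PDB / mmCIF
# dialects is delegated to bio3d; this module turns the flat atom table into
# per-chain residue records, normalizes modified residues, resolves alternate
# conformers and locates G-tracts and TTA/UUA loop triplets.

.water_names <- c("HOH", "WAT", "DOD", "H2O")
.ion_names <- c("K", "NA", "MG", "CA", "ZN", "CL", "BR", "SR", "TL",
                "CS", "MN", "BA", "NI")

.canonical_map <- c(
  DA = "A", DG = "G", DC = "C", DT = "T", DU = "U",
  A = "A", G = "G", C = "C", T = "T", U = "U"
)

#' Modified-residue alias table
#'
#' Maps modified residue names to their canonical parent base.  The shipped
#' table covers the brominated nucleotides found in telomeric quadruplex
#' crystal structures (e.g. 5-bromo-dU used for phasing); it is a plain CSV
#' (`name,parent`) so additional aliases can be supplied without touching
#' code.
#'
#' @param path Optional path to a replacement/extended CSV with columns
#'   `name` and `parent`.
#' @return Named character vector: alias name -> canonical base.
#' @export
residue_aliases <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "modified_residues.csv",
                        package = "g4loops", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(toupper(tab$parent), toupper(tab$name))
}

#' Canonicalize a residue name
#'
#' Maps an as-read residue name to one of the five canonical bases
#' A, G, C, T, U.  Standard DNA/RNA names map with `is_modified = FALSE`;
#' names in the alias table (e.g. brominated uridine, "BRU") map to their
#' parent base with `is_modified = TRUE`.  Unknown names are never silently
#' coerced: the return code is `NA` and a warning is raised so the caller
#' can exclude the residue.
#'
#' @param name As-read residue name (e.g. "DT", "BRU").
#' @param aliases Alias table from [residue_aliases()].
#' @return `list(code, is_modified)`; `code` is `NA_character_` for unknown
#'   names.
#' @export
normalize_residue <- function(name, aliases = residue_aliases()) {
  stopifnot(nzchar(name))
  key <- toupper(trimws(name))
  if (key %in% names(.canonical_map)) {
    return(list(code = unname(.canonical_map[key]), is_modified = FALSE))
  }
  if (key %in% names(aliases)) {
    return(list(code = unname(aliases[key]), is_modified = TRUE))
  }
  warning(sprintf("unknown residue name '%s': residue excluded", name),
          call. = FALSE)
  list(code = NA_character_, is_modified = FALSE)
}

#' Construct a residue record
#'
#' @param chain_id Chain identifier.
#' @param seq_num Author residue number.
#' @param code Canonical base code (A, G, C, T, U).
#' @param atoms Data frame with columns `name`, `element`, `x`, `y`, `z`,
#'   `occupancy`, `altloc`, `b_factor`.
#' @param icode Insertion code ("" when absent).
#' @param original_name As-read residue name.
#' @param is_modified Whether the residue was mapped through the alias table.
#' @return Object of class `residue_record`.
#' @export
residue_record <- function(chain_id, seq_num, code, atoms, icode = "",
                           original_name = code, is_modified = FALSE) {
  stopifnot(code %in% c("A", "G", "C", "T", "U"))
  stopifnot(all(c("name", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  structure(
    list(chain_id = chain_id, seq_num = as.integer(seq_num), icode = icode,
         code = code, original_name = original_name, atoms = atoms,
         is_modified = is_modified),
    class = "residue_record")
}

#' @export
print.residue_record <- function(x, ...) {
  cat(sprintf("Residue %s%s%d (%s -> %s)%s, %d atoms\n",
              x$chain_id, " ", x$seq_num, x$original_name, x$code,
              if (x$is_modified) " [modified]" else "",
              nrow(x$atoms)))
  invisible(x)
}

#' Construct a structure model
#'
#' @param structure_id Identifier (typically the PDB ID or file stem).
#' @param chains Named list (by chain id) of lists of `residue_record`s in
#'   5'->3' order.
#' @param model_num Model number (>= 1; NMR ensembles have several).
#' @param het Data frame of non-nucleotide records (waters, ions, ligands)
#'   retained as metadata only.
#' @param meta List with optional `resolution` (Angstrom) and `space_group`.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(structure_id, chains, model_num = 1L,
                            het = NULL, meta = list()) {
  stopifnot(model_num >= 1)
  structure(
    list(structure_id = structure_id, model_num = as.integer(model_num),
         chains = chains, het = het, meta = meta),
    class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure %s, model %d: %d chain(s)\n",
              x$structure_id, x$model_num, length(x$chains)))
  for (cid in names(x$chains)) {
    cat(sprintf("  chain %s: %d nt  %s\n", cid, length(x$chains[[cid]]),
                paste(vapply(x$chains[[cid]], `[[`, "", "code"),
                      collapse = "")))
  }
  invisible(x)
}

# sequence of canonical codes for one chain
chain_codes <- function(chain) vapply(chain, `[[`, character(1), "code")

#' Resolve alternate conformers of a residue
#'
#' For every atom name occurring with multiple alternate-location
#' indicators, the copy with the highest occupancy is kept; ties are broken
#' in favour of altloc "A" (then alphabetically).
#'
#' @param res A `residue_record`.
#' @return The residue with unique atom names.
#' @export
resolve_altlocs <- function(res) {
  a <- res$atoms
  if (!anyDuplicated(a$name)) return(res)
  alt <- a$altloc
  alt[is.na(alt) | alt == ""] <- "~"  # blank altloc sorts after letters
  keep <- unlist(lapply(split(seq_len(nrow(a)), a$name), function(idx) {
    if (length(idx) == 1) return(idx)
    occ <- a$occupancy[idx]
    cand <- idx[occ == max(occ)]
    cand[order(alt[cand])][1]
  }), use.names = FALSE)
  res$atoms <- a[sort(keep), , drop = FALSE]
  rownames(res$atoms) <- NULL
  res
}

# resolution / space group from PDB header lines (bio3d keeps coordinates
# only, so the two Table-1 style metadata fields are pulled from REMARK 2 /
# CRYST1 directly)
read_pdb_meta <- function(path) {
  lines <- readLines(path, n = 1000, warn = FALSE)
  res <- NA_real_
  sg <- NA_character_
  r2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(r2)) {
    m <- regmatches(r2[1], regexpr("[0-9]+\\.[0-9]+", r2[1]))
    if (length(m)) res <- as.numeric(m)
  }
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) && nchar(cr[1]) >= 56) {
    sg <- trimws(substr(cr[1], 56, min(66, nchar(cr[1]))))
    if (!nzchar(sg)) sg <- NA_character_
  }
  list(resolution = res, space_group = sg)
}

#' Read a coordinate file into structure models
#'
#' Parses a PDB (or mmCIF) file via bio3d and assembles one
#' `structure_model` per MODEL block.  Nucleotide residues (canonical or
#' alias-mapped, including HETATM-encoded modified nucleotides such as
#' bromo-dU) populate the chains; waters, metal ions, ligand heteroatoms and
#' unknown residue names are stored separately in `het` and excluded from
#' the chains (unknown names with a warning).
#'
#' @param path Path to the coordinate file.
#' @param dialect "pdb" (default) or "mmcif".
#' @param aliases Modified-residue alias table, see [residue_aliases()].
#' @return List of `structure_model`, one per model.
#' @export
read_structure <- function(path, dialect = c("pdb", "mmcif"),
                           aliases = residue_aliases()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pdb <- tryCatch(
    if (dialect == "pdb") {
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.cif(path, verbose = FALSE)
    },
    error = function(e) {
      stop(sprintf("cannot parse %s as %s: %s", path, dialect,
                   conditionMessage(e)), call. = FALSE)
    })
  atom <- pdb$atom
  if (is.null(atom) || nrow(atom) == 0) {
    stop(sprintf("cannot parse %s as %s: no atom records found", path,
                 dialect), call. = FALSE)
  }
  nmodels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  structure_id <- sub("\\.(pdb|ent|cif)$", "", basename(path),
                      ignore.case = TRUE)
  meta <- if (dialect == "pdb") read_pdb_meta(path) else list(
    resolution = NA_real_, space_group = NA_character_)

  resid_up <- toupper(trimws(atom$resid))
  known <- resid_up %in% c(names(.canonical_map), names(aliases))
  is_het_solvent <- resid_up %in% c(.water_names, .ion_names)
  unknown <- !known & !is_het_solvent
  if (any(unknown)) {
    ligand_like <- unique(resid_up[unknown])
    warning(sprintf("non-nucleotide residue(s) excluded from chains: %s",
                    paste(ligand_like, collapse = ", ")), call. = FALSE)
  }

  chain_raw <- atom$chain
  chain_raw[is.na(chain_raw)] <- " "
  insert <- atom$insert
  insert[is.na(insert)] <- ""
  res_key <- paste(chain_raw, atom$resno, insert, sep = "|")

  models <- vector("list", nmodels)
  for (m in seq_len(nmodels)) {
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[m, ] else as.numeric(pdb$xyz)
    coords <- matrix(xyz, ncol = 3, byrow = TRUE)
    chains <- list()
    empty_chains <- character(0)
    for (cid in unique(chain_raw)) {
      sel_chain <- which(chain_raw == cid & known)
      if (length(sel_chain) == 0) {
        if (any(chain_raw == cid & !is_het_solvent)) {
          empty_chains <- c(empty_chains, cid)
        }
        next
      }
      keys <- unique(res_key[sel_chain])
      residues <- list()
      for (k in keys) {
        idx <- which(res_key == k & known)
        nm <- normalize_residue(resid_up[idx[1]], aliases = aliases)
        if (is.na(nm$code)) next  # warning already raised by the name scan
        atoms <- data.frame(
          # legacy PDB files use * instead of ' in sugar atom names
          name = gsub("*", "'", trimws(atom$elety[idx]), fixed = TRUE),
          element = ifelse(is.na(atom$elesy[idx]), "",
                           trimws(atom$elesy[idx])),
          x = coords[idx, 1], y = coords[idx, 2], z = coords[idx, 3],
          occupancy = ifelse(is.na(atom$o[idx]), 1, atom$o[idx]),
          altloc = ifelse(is.na(atom$alt[idx]), "", atom$alt[idx]),
          b_factor = ifelse(is.na(atom$b[idx]), 0, atom$b[idx]),
          stringsAsFactors = FALSE)
        res <- residue_record(
          chain_id = cid, seq_num = atom$resno[idx[1]], code = nm$code,
          atoms = atoms, icode = insert[idx[1]],
          original_name = resid_up[idx[1]], is_modified = nm$is_modified)
        residues[[length(residues) + 1L]] <- resolve_altlocs(res)
      }
      if (length(residues)) chains[[cid]] <- residues
    }
    if (length(empty_chains)) {
      warning(sprintf("chain(s) with zero nucleotides skipped: %s",
                      paste(empty_chains, collapse = ", ")), call. = FALSE)
    }
    het <- atom[!known, c("resid", "resno", "chain", "elety"), drop = FALSE]
    models[[m]] <- structure_model(structure_id, chains, model_num = m,
                                   het = het, meta = meta)
  }
  models
}

#' Write a structure model as a PDB-format file
#'
#' Flattens the chains into a fixed-column PDB file (via bio3d's writer).
#' Coordinates are written to three decimals, matching the format's
#' precision.
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  rows <- list()
  for (cid in names(model$chains)) {
    for (res in model$chains[[cid]]) {
      a <- res$atoms
      rows[[length(rows) + 1L]] <- data.frame(
        elety = a$name, resid = residue_pdb_name(res), chain = cid,
        resno = res$seq_num, x = a$x, y = a$y, z = a$z,
        o = a$occupancy, b = a$b_factor, elesy = a$element,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("empty model: nothing to write")
  tab <- do.call(rbind, rows)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(tab[, c("x", "y", "z")]))),
                   resno = tab$resno, resid = tab$resid, chain = tab$chain,
                   eleno = seq_len(nrow(tab)), elety = tab$elety,
                   o = tab$o, b = tab$b, elesy = tab$elesy)
  invisible(path)
}

# PDB residue name for writing: original name if set, else DNA-style name
residue_pdb_name <- function(res) {
  if (!is.null(res$original_name) && nzchar(res$original_name)) {
    return(res$original_name)
  }
  if (res$code == "U") "U" else paste0("D", res$code)
}

#' Locate G-tracts in a model
#'
#' @param model A `structure_model`.
#' @param min_tract Minimum number of consecutive guanines forming a tract.
#' @return Named list (per chain) of data frames with columns `start`,
#'   `end` (1-based 5'->3' chain indices) and `seq_start`, `seq_end`
#'   (author numbering).
#' @export
find_gtracts <- function(model, min_tract = 3) {
  out <- list()
  for (cid in names(model$chains)) {
    chain <- model$chains[[cid]]
    codes <- chain_codes(chain)
    r <- rle(codes == "G")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values & r$lengths >= min_tract)
    out[[cid]] <- data.frame(
      start = starts[sel], end = ends[sel],
      seq_start = vapply(starts[sel], function(i) chain[[i]]$seq_num,
                         integer(1)),
      seq_end = vapply(ends[sel], function(i) chain[[i]]$seq_num,
                       integer(1)))
  }
  out
}

# atoms that must be present for a loop residue to count as resolved:
# the phosphate/sugar backbone plus the six-membered base ring
.required_backbone <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'",
                        "C1'", "C2'", "O4'")

residue_is_resolved <- function(res) {
  ring6 <- if (res$code %in% .purines) {
    c("C4", "C5", "C6", "N1", "C2", "N3")
  } else {
    c("N1", "C2", "N3", "C4", "C5", "C6")
  }
  all(c(.required_backbone, ring6) %in% res$atoms$name)
}

#' Construct a loop instance
#'
#' @param structure_id,model_num,chain_id Provenance of the loop.
#' @param residues List of exactly three `residue_record`s in 5'->3' order
#'   (roles L1, L2, L3); L1/L2 must be T or U, L3 must be A.
#' @param positions 1-based chain indices of the three residues.
#' @param flanking List with `prev` and `nxt` tract index ranges.
#' @param resolved Whether all residues pass the atom-completeness rule.
#' @return Object of class `loop_instance`.
#' @export
loop_instance <- function(structure_id, model_num, chain_id, residues,
                          positions, flanking, resolved = TRUE) {
  stopifnot(length(residues) == 3)
  codes <- vapply(residues, `[[`, character(1), "code")
  stopifnot(codes[1] %in% c("T", "U"), codes[2] %in% c("T", "U"),
            codes[3] == "A")
  structure(
    list(structure_id = structure_id, model_num = model_num,
         chain_id = chain_id, residues = residues,
         roles = c("L1", "L2", "L3"), positions = positions,
         flanking = flanking, resolved = resolved),
    class = "loop_instance")
}

#' @export
print.loop_instance <- function(x, ...) {
  cat(sprintf("Loop %s chain %s %s (%d-%d)%s\n", x$structure_id, x$chain_id,
              paste(vapply(x$residues, `[[`, "", "code"), collapse = ""),
              x$residues[[1]]$seq_num, x$residues[[3]]$seq_num,
              if (x$resolved) "" else " [unresolved]"))
  invisible(x)
}

#' Locate TTA/UUA loop triplets between G-tracts
#'
#' Per chain, maximal runs of at least `min_tract` consecutive guanines are
#' G-tracts; every inter-tract segment of exactly three residues matching
#' the pattern (T|U)(T|U)A becomes a `loop_instance`.  Residues 5' of the
#' first tract or 3' of the last are never loops.  Loops in which any
#' residue is missing backbone/sugar atoms or the six-membered base ring are
#' flagged `resolved = FALSE` so downstream statistics can exclude them.
#'
#' @param model A `structure_model`.
#' @param min_tract Minimum G-run length for a tract.
#' @return List of `loop_instance` objects (possibly empty).
#' @export
find_loops <- function(model, min_tract = 3) {
  loops <- list()
  tracts_all <- find_gtracts(model, min_tract = min_tract)
  for (cid in names(model$chains)) {
    chain <- model$chains[[cid]]
    codes <- chain_codes(chain)
    tr <- tracts_all[[cid]]
    if (is.null(tr) || nrow(tr) < 2) next
    for (i in seq_len(nrow(tr) - 1L)) {
      seg <- (tr$end[i] + 1L):(tr$start[i + 1L] - 1L)
      seg_codes <- paste(codes[seg], collapse = "")
      if (length(seg) == 3 && grepl("^[TU][TU]A$", seg_codes)) {
        residues <- chain[seg]
        loops[[length(loops) + 1L]] <- loop_instance(
          structure_id = model$structure_id, model_num = model$model_num,
          chain_id = cid, residues = residues, positions = seg,
          flanking = list(prev = c(tr$start[i], tr$end[i]),
                          nxt = c(tr$start[i + 1L], tr$end[i + 1L])),
          resolved = all(vapply(residues, residue_is_resolved, logical(1))))
      } else {
        warning(sprintf(
          "chain %s: inter-tract segment '%s' (positions %d-%d) does not match (T|U)(T|U)A",
          cid, seg_codes, min(seg), max(seg)), call. = FALSE)
      }
    }
  }
  loops
}
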