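# Structure containers and PDB / FASTA input-output.
#
# Everything downstream (Q, geometry, scaling) works at the C-alpha level,
# so a Structure is simply an ordered set of chains, each carrying one
# C-alpha coordinate and a one-letter residue code per residue.  Author
# (PDB) numbering is preserved alongside a contiguous internal index so
# that numbering gaps never corrupt sequence separations.

#' Construct a chain record
#'
#' @param chain_id Single-character chain identifier.
#' @param residue_codes Character vector of one-letter residue codes
#'   (`X` for unknown).
#' @param ca_coords Numeric matrix (n x 3) of C-alpha coordinates in
#'   Angstrom, in N-to-C residue order.
#' @param author_numbers Integer vector of original PDB residue numbers;
#'   may be non-contiguous.  Defaults to `1:n`.
#' @return An object of class `chain_record`.
#' @export
chain_record <- function(chain_id, residue_codes, ca_coords,
                         author_numbers = seq_along(residue_codes)) {
  ca_coords <- as_coords(ca_coords, "ca_coords")
  residue_codes <- toupper(as.character(residue_codes))
  author_numbers <- as.integer(author_numbers)
  n <- length(residue_codes)
  if (n < 1L) stop("a chain must contain at least one residue")
  if (nrow(ca_coords) != n || length(author_numbers) != n)
    stop("residue_codes, ca_coords and author_numbers must have equal length")
  structure(list(chain_id = as.character(chain_id)[1L],
                 residue_codes = residue_codes,
                 ca_coords = ca_coords,
                 author_numbers = author_numbers),
            class = "chain_record")
}

#' Construct a C-alpha structure
#'
#' @param chains List of [chain_record()] objects (ordered).
#' @param name Text label for the structure.
#' @param frame_index Non-negative integer; frame number for structures
#'   taken from multi-model files (0 for single structures).
#' @return An object of class `ca_structure`.
#' @export
ca_structure <- function(chains, name = "", frame_index = 0L) {
  if (inherits(chains, "chain_record")) chains <- list(chains)
  if (!length(chains) || !all(vapply(chains, inherits, TRUE, "chain_record")))
    stop("'chains' must be a non-empty list of chain_record objects")
  ids <- vapply(chains, `[[`, "", "chain_id")
  if (anyDuplicated(ids)) stop("duplicate chain identifiers: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(chains) <- ids
  structure(list(chains = chains, name = as.character(name),
                 frame_index = as.integer(frame_index)),
            class = "ca_structure")
}

#' @export
print.ca_structure <- function(x, ...) {
  cat(sprintf("<ca_structure '%s' frame %d: %d chain(s), %d residues>\n",
              x$name, x$frame_index, length(x$chains), n_residues(x)))
  for (ch in x$chains)
    cat(sprintf("  chain %s: %d residues [%d..%d]\n", ch$chain_id,
                length(ch$residue_codes), ch$author_numbers[1L],
                ch$author_numbers[length(ch$author_numbers)]))
  invisible(x)
}

#' Number of residues in a structure
#' @param s A `ca_structure`.
#' @param chain_id Optional chain; default counts all chains.
#' @return Integer residue count.
#' @export
n_residues <- function(s, chain_id = NULL) {
  stopifnot(inherits(s, "ca_structure"))
  if (!is.null(chain_id)) return(length(get_chain(s, chain_id)$residue_codes))
  sum(vapply(s$chains, function(ch) length(ch$residue_codes), 1L))
}

#' Stacked C-alpha coordinates
#'
#' @param s A `ca_structure`.
#' @param chain_id Optional vector of chain ids to restrict and order by.
#' @return n x 3 numeric matrix, chains concatenated in order.
#' @export
coords <- function(s, chain_id = NULL) {
  stopifnot(inherits(s, "ca_structure"))
  ids <- chain_id %||% names(s$chains)
  do.call(rbind, lapply(ids, function(id) get_chain(s, id)$ca_coords))
}

get_chain <- function(s, chain_id) {
  ch <- s$chains[[as.character(chain_id)]]
  if (is.null(ch))
    stop(sprintf("no chain '%s'; available: %s", chain_id,
                 paste(names(s$chains), collapse = ", ")))
  ch
}

# residues whose PDB residue name is an amino acid under bio3d's tables,
# plus the common selenomethionine alias handled explicitly.
aa3to1 <- function(resid3) {
  out <- suppressWarnings(bio3d::aa321(resid3))
  out[resid3 == "MSE"] <- "M"
  out[is.na(out) | !out %in% aa_alphabet()] <- "X"
  out
}

aa1to3 <- function(code1) {
  out <- suppressWarnings(bio3d::aa123(code1))
  out[is.na(out) | code1 == "X" | nchar(out) != 3L] <- "UNK"
  out
}

# Pre-validate coordinate fields of CA records so malformed files fail
# with the offending line number rather than with NA coordinates.
validate_pdb_ca_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_ca <- is_atom & trimws(substr(lines, 13L, 16L)) == "CA"
  idx <- which(is_ca)
  if (!length(idx)) stop(sprintf("'%s' contains no CA atoms", path))
  for (i in idx) {
    fields <- c(substr(lines[i], 31L, 38L), substr(lines[i], 39L, 46L),
                substr(lines[i], 47L, 54L))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop(sprintf("malformed coordinate field at line %d of '%s'", i, path))
  }
  invisible(TRUE)
}

#' Read C-alpha structures from a PDB file
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}), retaining only C-alpha
#' atoms.  Multi-MODEL files yield one structure per model.  Alternate
#' locations are resolved to the conformer with the highest occupancy
#' (ties broken in favour of altloc `A`); insertion-coded residues are
#' kept in file order.  Amino-acid names are mapped to one-letter codes
#' (selenomethionine to `M`); anything unrecognised becomes `X`.
#'
#' @param path Path to a PDB file.
#' @param model Optional integer vector of 1-based model numbers to keep.
#' @return A list of [ca_structure()] objects (one per model).
#' @export
read_structure <- function(path, model = NULL) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  validate_pdb_ca_lines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  keep <- trimws(at$elety) == "CA" & trimws(at$resid) != "CA"
  if (!any(keep)) stop(sprintf("'%s' contains no CA atoms", path))
  at <- at[keep, , drop = FALSE]
  at$chain[is.na(at$chain) | at$chain == ""] <- "A"
  xyz_cols <- unlist(lapply(which(keep), function(k) 3L * (k - 1L) + 1:3))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  xyz <- xyz[, xyz_cols, drop = FALSE]

  # resolve altlocs per (chain, resno, insert): highest occupancy, tie -> 'A'
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  res_key <- paste(at$chain, at$resno, at$insert, sep = "|")
  ord <- order(match(res_key, unique(res_key)), -at$o, at$alt)
  first <- !duplicated(res_key[ord])
  sel <- sort(ord[first])
  at <- at[sel, , drop = FALSE]
  xyz <- xyz[, unlist(lapply(sel, function(k) 3L * (k - 1L) + 1:3)),
             drop = FALSE]

  n_model <- nrow(xyz)
  models <- model %||% seq_len(n_model)
  if (any(models < 1L | models > n_model))
    stop(sprintf("model index out of range; file has %d model(s)", n_model))
  chains_ids <- unique(at$chain)
  nm <- sub("\\.pdb$", "", basename(path))
  lapply(models, function(m) {
    chs <- lapply(chains_ids, function(cid) {
      rows <- which(at$chain == cid)
      cc <- matrix(xyz[m, unlist(lapply(rows, function(k) 3L * (k - 1L) + 1:3))],
                   ncol = 3L, byrow = TRUE)
      chain_record(chain_id = if (is.na(cid) || cid == "") "A" else cid,
                   residue_codes = aa3to1(trimws(at$resid[rows])),
                   ca_coords = cc,
                   author_numbers = at$resno[rows])
    })
    ca_structure(chs, name = nm, frame_index = m - 1L)
  })
}

#' Write C-alpha-only PDB
#'
#' Writes one structure, or a list of structures with identical layout as
#' a multi-MODEL file, using fixed-width ATOM records (3-decimal
#' coordinates, the PDB precision).
#'
#' @param s A `ca_structure` or a list of them.
#' @param path Output path.
#' @param header Optional character vector of REMARK lines (text only;
#'   `REMARK   ` is prefixed).
#' @return Invisibly, `path`.
#' @export
write_structure <- function(s, path, header = NULL) {
  if (inherits(s, "ca_structure")) s <- list(s)
  stopifnot(all(vapply(s, inherits, TRUE, "ca_structure")))
  multi <- length(s) > 1L
  out <- character(0)
  if (!is.null(header)) out <- c(out, paste0("REMARK   ", header))
  for (m in seq_along(s)) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    serial <- 0L
    for (ch in s[[m]]$chains) {
      res3 <- aa1to3(ch$residue_codes)
      for (i in seq_along(res3)) {
        serial <- serial + 1L
        out <- c(out, sprintf(
          "ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, res3[i], substr(ch$chain_id, 1L, 1L),
          ch$author_numbers[i],
          ch$ca_coords[i, 1L], ch$ca_coords[i, 2L], ch$ca_coords[i, 3L],
          1, 0))
      }
      out <- c(out, "TER")
    }
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Extract a chain's one-letter sequence
#'
#' @param s A `ca_structure`.
#' @param chain_id Chain identifier.
#' @return Single string of one-letter codes (length = residue count).
#' @export
extract_sequence <- function(s, chain_id) {
  paste(get_chain(s, chain_id)$residue_codes, collapse = "")
}

#' Declare a residue segment
#'
#' Segments (such as the alpha2 helix of a histone fold) are explicit
#' user input: bounds plus whether they refer to author (PDB) numbering
#' or to the contiguous internal 1-based index.
#'
#' @param chain_id Chain identifier.
#' @param start,end Inclusive bounds, `start <= end`.
#' @param indexing `"author"` (default) or `"internal"`.
#' @return An object of class `segment_spec`.
#' @export
segment_spec <- function(chain_id, start, end,
                         indexing = c("author", "internal")) {
  indexing <- match.arg(indexing)
  start <- as.integer(start); end <- as.integer(end)
  if (start > end) stop("'start' must not exceed 'end'")
  structure(list(chain_id = as.character(chain_id), start = start,
                 end = end, indexing = indexing), class = "segment_spec")
}

#' Select a residue segment from a structure
#'
#' @param s A `ca_structure`.
#' @param spec A [segment_spec()].
#' @return List with `coords` (n x 3, N-to-C order), `sequence` (string)
#'   and `author_numbers`.
#' @export
select_segment <- function(s, spec) {
  stopifnot(inherits(spec, "segment_spec"))
  ch <- get_chain(s, spec$chain_id)
  n <- length(ch$residue_codes)
  if (spec$indexing == "internal") {
    if (spec$start < 1L || spec$end > n)
      stop(sprintf("internal range [%d, %d] outside 1..%d", spec$start,
                   spec$end, n))
    idx <- spec$start:spec$end
  } else {
    idx <- which(ch$author_numbers >= spec$start &
                   ch$author_numbers <= spec$end)
    if (!length(idx))
      stop(sprintf("author range [%d, %d] selects no residues; chain %s spans %d..%d",
                   spec$start, spec$end, spec$chain_id,
                   min(ch$author_numbers), max(ch$author_numbers)))
  }
  if (length(idx) < 3L)
    stop(sprintf("segment resolves to %d residue(s); at least 3 are required",
                 length(idx)))
  list(coords = ch$ca_coords[idx, , drop = FALSE],
       sequence = paste(ch$residue_codes[idx], collapse = ""),
       author_numbers = ch$author_numbers[idx])
}

#' Enumerate chain correspondences between two structures
#'
#' For homodimers (two chains of equal length) chain assignment is
#' ambiguous, so scores such as Q must be maximised over all
#' length-preserving bijections of chain labels.  This enumerates them.
#'
#' @param a,b `ca_structure` objects with equal chain counts.
#' @return List of named character vectors; each maps chain ids of `a`
#'   to the corresponding chain ids of `b`.
#' @export
enumerate_chain_pairings <- function(a, b) {
  stopifnot(inherits(a, "ca_structure"), inherits(b, "ca_structure"))
  ids_a <- names(a$chains); ids_b <- names(b$chains)
  if (length(ids_a) != length(ids_b))
    stop("structures have different chain counts")
  len_a <- vapply(ids_a, function(i) n_residues(a, i), 1L)
  len_b <- vapply(ids_b, function(i) n_residues(b, i), 1L)
  perms <- permutations_of(seq_along(ids_b))
  out <- list()
  for (p in perms) {
    if (all(len_a == len_b[p])) {
      m <- ids_b[p]; names(m) <- ids_a
      out[[length(out) + 1L]] <- m
    }
  }
  if (!length(out))
    stop("no length-preserving chain correspondence between the structures")
  out
}

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutations_of(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

#' Read sequences from a FASTA file
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  fa <- bio3d::read.fasta(path, rm.dup = FALSE)
  out <- apply(fa$ali, 1L, function(r) paste(r[r != "-"], collapse = ""))
  stats::setNames(toupper(out), rownames(fa$ali))
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  nm <- names(seqs) %||% paste0("seq", seq_along(seqs))
  writeLines(as.vector(rbind(paste0(">", nm), unname(seqs))), path)
  invisible(path)
}
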