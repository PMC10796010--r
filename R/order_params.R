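# Native-contact reference construction and the Q order parameter.
#
# Q = (1/N) * sum_{pairs} exp[ -(r_ij - r_ij^N)^2 / (2 sigma_ij^2) ]
#
# where the pair set runs over residue pairs with sequence separation
# |i - j| >= 3 within a chain (the "i < j - 2" rule), optionally plus all
# inter-chain pairs (dimer mode) or inter-chain pairs only (interface
# mode).  r_ij^N are the native C-alpha distances; sigma_ij grows slowly
# with sequence separation, sigma_ij = sigma_base * (1 + |i - j|)^0.15,
# and is held constant for inter-chain pairs where |i - j| has no
# meaning.  Q is 1 on the native structure and decays towards 0 as
# internal distances deviate; it is invariant under rigid motion because
# only internal distances enter.

#' Q calculation settings
#'
#' @param mode `"monomer"` (intra-chain pairs), `"dimer"` (intra plus all
#'   inter-chain pairs) or `"interface"` (inter-chain pairs only,
#'   restricted to native distance <= `interface_native_cutoff`).
#' @param sigma_exponent Exponent of the pair-width growth law
#'   (default 0.15).
#' @param sigma_base Base pair width in Angstrom (default 1).
#' @param interface_native_cutoff Native-distance cutoff (Angstrom)
#'   defining interface pairs (default 9.5; use `Inf` for the literal
#'   all-inter-pairs variant).
#' @param min_separation Minimum intra-chain sequence separation
#'   (default 3, i.e. pairs with `j - i >= 3`).
#' @return An object of class `q_spec`.
#' @export
q_spec <- function(mode = c("monomer", "dimer", "interface"),
                   sigma_exponent = 0.15, sigma_base = 1,
                   interface_native_cutoff = 9.5, min_separation = 3L) {
  mode <- match.arg(mode)
  stopifnot(sigma_exponent > 0 || mode == mode, sigma_base > 0,
            interface_native_cutoff > 0, min_separation >= 1L)
  structure(list(mode = mode, sigma_exponent = sigma_exponent,
                 sigma_base = sigma_base,
                 interface_native_cutoff = interface_native_cutoff,
                 min_separation = as.integer(min_separation)),
            class = "q_spec")
}

chain_index_table <- function(s) {
  do.call(rbind, lapply(names(s$chains), function(cid) {
    n <- n_residues(s, cid)
    data.frame(chain = rep(cid, n), idx = seq_len(n),
               stringsAsFactors = FALSE)
  }))
}

#' Build a native-contact reference
#'
#' Enumerates the residue pairs entering Q for a given native structure
#' and mode, with their native distances and pair widths.  Residue
#' indices are the contiguous internal 1-based indices within each chain
#' (author numbering gaps never enter sequence separations).
#'
#' @param native A `ca_structure`.
#' @param spec A [q_spec()].
#' @return An object of class `contact_reference`: data frame with
#'   columns `chain_a`, `i`, `chain_b`, `j`, `r_native`, `sigma`,
#'   `class` (`"intra"`/`"inter"`), carrying the spec as an attribute.
#' @export
build_contact_reference <- function(native, spec = q_spec()) {
  stopifnot(inherits(native, "ca_structure"), inherits(spec, "q_spec"))
  ids <- names(native$chains)
  if (spec$mode != "monomer" && length(ids) < 2L)
    stop(sprintf("mode '%s' requires at least 2 chains", spec$mode))
  rows <- list()
  if (spec$mode %in% c("monomer", "dimer")) {
    for (cid in ids) {
      cc <- native$chains[[cid]]$ca_coords
      n <- nrow(cc)
      if (n < spec$min_separation + 1L) next
      ij <- which(outer(seq_len(n), seq_len(n),
                        function(i, j) j - i >= spec$min_separation),
                  arr.ind = TRUE)
      sep <- ij[, 2L] - ij[, 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        chain_a = cid, i = ij[, 1L], chain_b = cid, j = ij[, 2L],
        r_native = sqrt(rowSums((cc[ij[, 1L], , drop = FALSE] -
                                   cc[ij[, 2L], , drop = FALSE])^2)),
        sigma = spec$sigma_base * (1 + sep)^spec$sigma_exponent,
        class = "intra", stringsAsFactors = FALSE)
    }
  }
  if (spec$mode %in% c("dimer", "interface")) {
    sigma_inter <- spec$sigma_base *
      (1 + spec$min_separation)^spec$sigma_exponent
    pairs <- utils::combn(ids, 2L, simplify = FALSE)
    for (p in pairs) {
      ca <- native$chains[[p[1L]]]$ca_coords
      cb <- native$chains[[p[2L]]]$ca_coords
      ij <- expand.grid(i = seq_len(nrow(ca)), j = seq_len(nrow(cb)))
      r <- sqrt(rowSums((ca[ij$i, , drop = FALSE] -
                           cb[ij$j, , drop = FALSE])^2))
      keep <- if (spec$mode == "interface")
        r <= spec$interface_native_cutoff else rep(TRUE, length(r))
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chain_a = p[1L], i = ij$i[keep], chain_b = p[2L], j = ij$j[keep],
        r_native = r[keep], sigma = sigma_inter, class = "inter",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no contact pairs under this spec")
  ref <- do.call(rbind, rows)
  rownames(ref) <- NULL
  attr(ref, "q_spec") <- spec
  class(ref) <- c("contact_reference", "data.frame")
  ref
}

ref_distances <- function(conformation, reference, pairing = NULL) {
  ids_needed <- unique(c(reference$chain_a, reference$chain_b))
  map <- pairing %||% stats::setNames(ids_needed, ids_needed)
  get_cc <- function(cid) {
    mapped <- map[[cid]]
    if (is.null(mapped) || is.na(mapped))
      stop(sprintf("pairing does not map reference chain '%s'", cid))
    get_chain(conformation, mapped)$ca_coords
  }
  ccs <- lapply(stats::setNames(ids_needed, ids_needed), get_cc)
  for (cid in ids_needed) {
    need <- max(reference$i[reference$chain_a == cid],
                reference$j[reference$chain_b == cid], 0L)
    if (nrow(ccs[[cid]]) < need)
      stop(sprintf(
        "conformation chain '%s' has %d residues but the reference needs %d",
        map[[cid]], nrow(ccs[[cid]]), need))
  }
  a <- do.call(rbind, lapply(seq_len(nrow(reference)), function(k)
    ccs[[reference$chain_a[k]]][reference$i[k], ]))
  b <- do.call(rbind, lapply(seq_len(nrow(reference)), function(k)
    ccs[[reference$chain_b[k]]][reference$j[k], ]))
  sqrt(rowSums((a - b)^2))
}

#' The Q structural-similarity order parameter
#'
#' @param conformation A `ca_structure` providing every residue named by
#'   the reference (under the chain pairing).
#' @param reference A [build_contact_reference()] result.
#' @param pairing Optional named character vector mapping reference chain
#'   ids to conformation chain ids (see [enumerate_chain_pairings()]);
#'   identity by default.  For homodimers, maximise over pairings with
#'   [q_score_max()].
#' @return Q in \[0, 1\].
#' @export
q_score <- function(conformation, reference, pairing = NULL) {
  stopifnot(inherits(reference, "contact_reference"))
  r <- ref_distances(conformation, reference, pairing)
  mean(exp(-(r - reference$r_native)^2 / (2 * reference$sigma^2)))
}

#' Q maximised over chain pairings
#'
#' @inheritParams q_score
#' @param native The native `ca_structure` the reference was built from
#'   (used to enumerate label bijections).
#' @return List with `q` (the maximum) and `pairing`.
#' @export
q_score_max <- function(conformation, reference, native) {
  pairings <- enumerate_chain_pairings(native, conformation)
  qs <- vapply(pairings, function(p) q_score(conformation, reference, p), 1.0)
  k <- which.max(qs)
  list(q = qs[k], pairing = pairings[[k]])
}

#' Q over an ensemble of conformations
#'
#' @param frames List of `ca_structure` objects.
#' @inheritParams q_score
#' @return Numeric vector of Q values.
#' @export
q_series <- function(frames, reference, pairing = NULL) {
  if (inherits(frames, "ca_structure")) frames <- list(frames)
  vapply(frames, q_score, 1.0, reference = reference, pairing = pairing)
}

#' Fraction of native contacts
#'
#' A native contact is a residue pair (sequence separation >= 3 within a
#' chain, plus every inter-chain pair) whose native C-alpha distance is
#' at most `contact_cutoff`.  The contact counts as formed in the
#' conformation when its distance there is at most
#' `tolerance_factor * contact_cutoff`.
#'
#' @param conformation,native `ca_structure` objects with the same
#'   chain/residue layout.
#' @param contact_cutoff Native contact distance cutoff in Angstrom
#'   (default 8).
#' @param tolerance_factor Multiplier on the cutoff for a contact to
#'   count as formed (default 1.2).
#' @param pairing Optional chain pairing as in [q_score()].
#' @return Fraction in \[0, 1\].
#' @export
fraction_native_contacts <- function(conformation, native,
                                     contact_cutoff = 8,
                                     tolerance_factor = 1.2,
                                     pairing = NULL) {
  if (contact_cutoff <= 0) stop("'contact_cutoff' must be positive")
  mode <- if (length(native$chains) > 1L) "dimer" else "monomer"
  ref <- build_contact_reference(native, q_spec(mode, min_separation = 3L))
  ref <- ref[ref$r_native <= contact_cutoff, , drop = FALSE]
  if (!nrow(ref)) stop("the native structure has no contacts at this cutoff")
  r <- ref_distances(conformation, ref, pairing)
  mean(r <= tolerance_factor * contact_cutoff)
}

#' Write a contact reference to TSV
#' @param reference A `contact_reference`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contact_reference <- function(reference, path) {
  utils::write.table(as.data.frame(reference), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
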