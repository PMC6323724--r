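# Probe-style detection of inter-chain residue contacts in two-chain
# dimer structures, cross-taxon/template consensus calling of interface
# positions, and per-Group residue frequency (logo) matrices.

#' Default van der Waals radii by element (Angstrom)
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.10, P = 1.80)
}

# atoms forming the peptide backbone (clash-exclusion rule)
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a two-chain structure object
#'
#' @param id structure identifier
#' @param taxon taxon of origin
#' @param template crystal-template label, one of [DIMER_TEMPLATES]
#'   (prefix `G:` or `NC:` names the interface the template exposes)
#' @param atoms data frame with columns chain, resno, resname, atom,
#'   element, x, y, z
#' @return list of class "septin_structure"
#' @export
septin_structure <- function(id, taxon, template, atoms) {
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    abort(sprintf("atoms must have columns %s", paste(need, collapse = ", ")))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  structure(list(id = id, taxon = taxon, template = template,
                 atoms = atoms), class = "septin_structure")
}

#' Read a two-chain structure from a PDB file
#'
#' Fixed-column ATOM records via bio3d; first model only, alternate
#' locations restricted to ' ' or 'A'. Hydrogens are kept if present but
#' never added.
#'
#' @param path PDB file
#' @param taxon,template metadata to attach (see [septin_structure()])
#' @return a "septin_structure"
#' @export
read_structure_pdb <- function(path, taxon = NA_character_,
                               template = NA_character_) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & (is.na(at$alt) | at$alt %in% c("", "A")), ]
  elem <- at$elesy
  missing_e <- is.na(elem) | elem == ""
  elem[missing_e] <- substr(gsub("[0-9]", "", at$elety[missing_e]), 1, 1)
  septin_structure(
    id = basename(path), taxon = taxon, template = template,
    atoms = data.frame(chain = at$chain, resno = at$resno,
                       resname = at$resid, atom = at$elety,
                       element = elem, x = at$x, y = at$y, z = at$z,
                       stringsAsFactors = FALSE))
}

#' Write a structure as a minimal PDB file
#'
#' Plain fixed-column ATOM records, chains as given, element column set.
#'
#' @param structure a "septin_structure"
#' @param path output file
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
    a$resname, a$chain, a$resno, a$x, a$y, a$z, a$element)
  writeLines(c(lines, "END"), path)
  invisible(NULL)
}

#' Detect inter-chain residue contacts (probe-style)
#'
#' An atom pair (one atom per chain) interacts when its distance is at
#' most r_i + r_j + `probe_diameter` (boundary inclusive); intra-chain
#' pairs are ignored (the one-way rule). Pairs where both atoms belong to
#' the peptide backbone and overlap (distance < r_i + r_j) are discarded
#' as modelling clashes. Surviving atom pairs are collapsed to residue
#' pairs, keeping the minimal gap (distance - r_i - r_j) per pair.
#'
#' @param structure a "septin_structure" with exactly two chains
#' @param probe_diameter probe diameter in Angstrom (default 0.5)
#' @param radii named per-element van der Waals radii
#' @param backbone_atoms atom names treated as backbone
#' @return data frame (chain_a, resno_a, chain_b, resno_b, min_gap,
#'   n_atom_pairs, interface) — `interface` from the template label
#' @export
detect_contacts <- function(structure, probe_diameter = 0.5,
                            radii = vdw_radii(),
                            backbone_atoms = BACKBONE_ATOMS) {
  check_scalar_number(probe_diameter, "probe_diameter", lower = 0)
  at <- structure$atoms
  chains <- sort(unique(at$chain))
  if (length(chains) != 2L) {
    abort("structure must have exactly two chains")
  }
  A <- at[at$chain == chains[1], ]
  B <- at[at$chain == chains[2], ]
  rA <- radii[A$element]
  rB <- radii[B$element]
  if (anyNA(rA) || anyNA(rB)) {
    abort("unknown element: extend `radii`")
  }
  # all inter-chain pairwise distances
  dx <- outer(A$x, B$x, "-")
  dy <- outer(A$y, B$y, "-")
  dz <- outer(A$z, B$z, "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  rsum <- outer(unname(rA), unname(rB), "+")
  eps <- 1e-9  # boundary-inclusive threshold, robust to FP rounding
  hit <- d <= rsum + probe_diameter + eps
  bbA <- A$atom %in% backbone_atoms
  bbB <- B$atom %in% backbone_atoms
  clash <- outer(bbA, bbB, "&") & (d < rsum - eps)
  hit <- hit & !clash
  ij <- which(hit, arr.ind = TRUE)
  iface <- sub(":.*$", "", structure$template %||% NA_character_)
  if (nrow(ij) == 0L) {
    return(data.frame(chain_a = character(0), resno_a = integer(0),
                      chain_b = character(0), resno_b = integer(0),
                      min_gap = numeric(0), n_atom_pairs = integer(0),
                      interface = character(0), stringsAsFactors = FALSE))
  }
  gaps <- d[ij] - rsum[ij]
  key <- paste(A$resno[ij[, 1]], B$resno[ij[, 2]], sep = "_")
  agg_min <- tapply(gaps, key, min)
  agg_n <- tapply(gaps, key, length)
  parts <- do.call(rbind, strsplit(names(agg_min), "_"))
  out <- data.frame(chain_a = chains[1],
                    resno_a = as.integer(parts[, 1]),
                    chain_b = chains[2],
                    resno_b = as.integer(parts[, 2]),
                    min_gap = as.numeric(agg_min),
                    n_atom_pairs = as.integer(agg_n),
                    interface = iface, stringsAsFactors = FALSE)
  out[order(out$resno_a, out$resno_b), , drop = FALSE]
}

#' Deduplicate contacts to the set of interacting residues
#'
#' @param contacts data frame from [detect_contacts()]
#' @return data frame (chain, resno) of residues appearing in any contact
#' @export
residue_interface_set <- function(contacts) {
  res <- rbind(data.frame(chain = contacts$chain_a,
                          resno = contacts$resno_a),
               data.frame(chain = contacts$chain_b,
                          resno = contacts$resno_b))
  unique(res[order(res$chain, res$resno), , drop = FALSE])
}

#' Tabulate interacting residues for a set of structures
#'
#' Runs [detect_contacts()] and [residue_interface_set()] on every
#' structure and returns one row per (taxon, template, residue number).
#' Chains are merged: homologous residues of the two chains share their
#' taxon numbering.
#'
#' @param structures list of "septin_structure" objects
#' @param probe_diameter,radii passed to [detect_contacts()]
#' @return data frame (taxon, template, interface, resno)
#' @export
structure_residue_table <- function(structures, probe_diameter = 0.5,
                                    radii = vdw_radii()) {
  rows <- lapply(structures, function(s) {
    contacts <- detect_contacts(s, probe_diameter, radii)
    res <- residue_interface_set(contacts)
    if (nrow(res) == 0L) return(NULL)
    data.frame(taxon = s$taxon, template = s$template,
               interface = sub(":.*$", "", s$template),
               resno = sort(unique(res$resno)), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(taxon = character(0), template = character(0),
                      interface = character(0), resno = integer(0)))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Aggregate per-taxon interface residues into a cross-taxon consensus
#'
#' Each taxon's residue numbers are translated into reference coordinates
#' through its alignment row (residues falling on reference-gap columns
#' are dropped, with a logged count). For every (reference position,
#' interface type), interacting taxa are counted per template; the
#' maximum over templates of that interface is the position's support,
#' and the position is a consensus interface residue when that maximum
#' reaches `min_taxa` (default 10) of `n_taxa` (default 17) — interaction
#' in at least 10 of the 17 taxa in at least one crystal template.
#'
#' @param residue_table data frame (taxon, template, interface, resno),
#'   e.g. from [structure_residue_table()]
#' @param alignment named gapped strings containing every taxon row plus
#'   the reference row
#' @param reference_id reference row id
#' @param n_taxa panel size (default: number of distinct taxa present)
#' @param min_taxa consensus threshold (default 10)
#' @return data frame (position, interface, max_count, proportion,
#'   consensus, plus one count column per template); attribute
#'   `n_unmapped` counts residues dropped at reference gaps
#' @export
aggregate_interfaces <- function(residue_table, alignment, reference_id,
                                 n_taxa = NULL, min_taxa = 10L) {
  alignment <- as_alignment(alignment)
  refmap <- map_to_reference(alignment, reference_id)
  taxa <- unique(residue_table$taxon)
  missing <- setdiff(taxa, names(alignment))
  if (length(missing) > 0) {
    abort(sprintf("taxa absent from alignment: %s",
                  paste(missing, collapse = ", ")),
          "septinevo_mapping_error")
  }
  n_taxa <- n_taxa %||% length(taxa)
  n_unmapped <- 0L
  mapped <- lapply(taxa, function(tx) {
    cols_tx <- row_residue_columns(alignment, tx)
    sub <- residue_table[residue_table$taxon == tx, , drop = FALSE]
    col <- cols_tx[sub$resno]
    ref <- refmap$col_to_res[as.character(col)]
    drop <- is.na(ref)
    n_unmapped <<- n_unmapped + sum(drop)
    cbind(sub[!drop, , drop = FALSE], position = as.integer(ref[!drop]))
  })
  tab <- do.call(rbind, mapped)
  templates <- sort(unique(residue_table$template))
  if (is.null(tab) || nrow(tab) == 0L) {
    out <- data.frame(position = integer(0), interface = character(0),
                      max_count = integer(0), proportion = numeric(0),
                      consensus = logical(0))
    attr(out, "n_unmapped") <- n_unmapped
    return(out)
  }
  combos <- unique(tab[, c("position", "interface")])
  counts <- matrix(0L, nrow(combos), length(templates),
                   dimnames = list(NULL, templates))
  for (k in seq_len(nrow(combos))) {
    sel <- tab$position == combos$position[k] &
      tab$interface == combos$interface[k]
    cnt <- tapply(tab$taxon[sel], tab$template[sel],
                  function(z) length(unique(z)))
    counts[k, names(cnt)] <- as.integer(cnt)
  }
  max_count <- apply(counts, 1, max)
  out <- data.frame(position = combos$position,
                    interface = combos$interface,
                    max_count = as.integer(max_count),
                    proportion = max_count / n_taxa,
                    consensus = max_count >= min_taxa,
                    stringsAsFactors = FALSE)
  out <- cbind(out, counts)
  out <- out[order(out$interface, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Per-Group residue frequency (logo) matrices at selected positions
#'
#' For each Group and reference position, the residue frequency vector
#' over that Group's member sequences (with the gap fraction tracked as
#' its own entry, so frequencies sum to 1 over residues + gap), plus the
#' per-position information content `max_bits - H` with H the Shannon
#' entropy (bits) of the non-gap residue distribution. Suitable as
#' direct sequence-logo input.
#'
#' @param alignment named gapped strings
#' @param group_assignment named character vector: sequence id -> Group
#' @param positions reference positions to profile
#' @param reference_id reference row id
#' @param max_bits information-content ceiling (default 2)
#' @return named list per Group: list(freq: 21 x positions matrix
#'   (20 residues + "-"), info: per-position information content)
#' @export
group_frequency_profiles <- function(alignment, group_assignment,
                                     positions, reference_id,
                                     max_bits = 2) {
  alignment <- as_alignment(alignment)
  refmap <- map_to_reference(alignment, reference_id)
  cols <- refmap$res_to_col[as.character(positions)]
  if (anyNA(cols)) {
    abort("some positions exceed the reference length",
          "septinevo_mapping_error")
  }
  M <- aln_matrix(alignment)
  rownames(M) <- names(alignment)
  out <- list()
  for (g in unique(group_assignment)) {
    members <- names(group_assignment)[group_assignment == g]
    members <- intersect(members, rownames(M))
    if (length(members) == 0L) {
      warning(sprintf("Group '%s' has no sequences in the alignment; skipped",
                      g))
      next
    }
    sub <- M[members, cols, drop = FALSE]
    freq <- vapply(seq_along(cols), function(j) {
      v <- sub[, j]
      res <- table(factor(v, levels = c(AA20, "-")))
      as.numeric(res) / length(v)
    }, numeric(21))
    rownames(freq) <- c(AA20, "-")
    colnames(freq) <- as.character(positions)
    info <- vapply(seq_along(cols), function(j) {
      p <- freq[seq_len(20), j]
      if (sum(p) == 0) return(0)
      p <- p / sum(p)
      nz <- p > 0
      max_bits - (-sum(p[nz] * log2(p[nz])))
    }, numeric(1))
    names(info) <- as.character(positions)
    out[[g]] <- list(freq = freq, info = info)
  }
  out
}

#' Cluster consensus positions into interacting groups
#'
#' Maximal runs of sorted reference positions where successive positions
#' differ by at most `max_gap` form one interacting group (ig), numbered
#' along the sequence.
#'
#' @param positions integer reference positions (sorted or not)
#' @param max_gap maximal within-group spacing (default 3)
#' @return data frame (ig, start, end, n_positions)
#' @export
interface_cluster <- function(positions, max_gap = 3L) {
  check_scalar_number(max_gap, "max_gap", lower = 0)
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) == 0L) {
    return(data.frame(ig = integer(0), start = integer(0),
                      end = integer(0), n_positions = integer(0)))
  }
  brk <- c(0L, cumsum(diff(positions) > max_gap))
  split_pos <- split(positions, brk)
  data.frame(ig = seq_along(split_pos),
             start = vapply(split_pos, min, integer(1)),
             end = vapply(split_pos, max, integer(1)),
             n_positions = vapply(split_pos, length, integer(1)),
             row.names = NULL)
}
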