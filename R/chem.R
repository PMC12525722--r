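# Molecule parsing and featurization.
#
# SMILES strings are converted to V2000 molfiles by OpenBabel (via
# ChemmineOB); the atom/bond blocks are then read into a light molecular
# graph with the minimal categorical featurization used throughout the
# package: per atom an atomic-number index plus a chirality tag, per bond a
# bond-type code plus a bond-direction code.

# IUPAC element symbols, position = atomic number
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

# featurization vocabulary sizes; the final atom-type index is a reserved
# mask token used by the atom-masking pretraining task
.NUM_ATOM_TYPES <- 119L   # atomic numbers 1..118 + mask token at 119
.ATOM_MASK_TOKEN <- 119L
.NUM_CHIRALITY <- 4L      # none / clockwise / counter-clockwise / other
.NUM_BOND_TYPES <- 6L     # single double triple aromatic self-loop other
.BOND_SELF_LOOP <- 5L
.NUM_BOND_DIRS <- 4L      # none / wedge-up / wedge-down / other

.ob_convert <- function(from, to, text) {
  ChemmineOB::convertFormat(from, to, source = text)
}

.molfile_records <- function(sdf_text) {
  recs <- strsplit(sdf_text, "\\$\\$\\$\\$\n?")[[1]]
  recs[nzchar(trimws(recs))]
}

# Read the atom and bond block of a single V2000 molfile record.
.read_v2000 <- function(record) {
  lines <- strsplit(record, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NULL)
  counts <- lines[4L]
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L) return(NULL)
  atom_lines <- lines[4L + seq_len(natoms)]
  fields <- strsplit(trimws(atom_lines), "\\s+")
  element <- vapply(fields, function(f) f[[4L]], character(1))
  parity <- vapply(fields, function(f) {
    v <- suppressWarnings(as.integer(f[7L]))
    if (is.na(v)) 0L else v
  }, integer(1))
  bonds <- NULL
  if (nbonds > 0L) {
    bond_lines <- lines[4L + natoms + seq_len(nbonds)]
    bi <- as.integer(substr(bond_lines, 1L, 3L))
    bj <- as.integer(substr(bond_lines, 4L, 6L))
    bo <- as.integer(substr(bond_lines, 7L, 9L))
    bs <- suppressWarnings(as.integer(substr(bond_lines, 10L, 12L)))
    bs[is.na(bs)] <- 0L
    bonds <- data.frame(i = bi, j = bj, order = bo, stereo = bs)
  }
  list(natoms = natoms, element = element, parity = parity, bonds = bonds)
}

.bond_type_code <- function(order) {
  # 1 single, 2 double, 3 triple, 4 aromatic, else "other"
  ifelse(order %in% 1:4, order, 6L)
}

.bond_dir_code <- function(stereo) {
  # molfile bond stereo: 0 none, 1 wedge up, 6 wedge down
  out <- rep.int(1L, length(stereo))
  out[stereo == 1L] <- 2L
  out[stereo == 6L] <- 3L
  out[!(stereo %in% c(0L, 1L, 6L))] <- 4L
  out
}

#' Parse a SMILES string into a molecular graph
#'
#' Converts one SMILES string into an attributed molecular graph over heavy
#' atoms: node features are the atomic-number index (1-118) and a chirality
#' tag, edge features are the bond-type code (single/double/triple/aromatic)
#' and a bond-direction code. Hydrogens are implicit. Parsing is delegated to
#' OpenBabel, so any SMILES dialect OpenBabel accepts is accepted here.
#'
#' @param smiles A single non-empty SMILES string.
#' @return An object of class `mol_graph` with elements `n_atoms`, `element`,
#'   `atom_type` (atomic-number index), `chirality`, `bonds` (data frame with
#'   columns `i`, `j`, `type`, `dir`; one row per undirected bond, `i < j`)
#'   and `smiles`. On unparseable input, an object of class
#'   `smiles_parse_failure` is returned instead so callers can drop the
#'   record; test with [is_mol_graph()].
#' @examples
#' g <- parse_smiles("CCO")
#' g$n_atoms        # 3 heavy atoms
#' nrow(g$bonds)    # 2 bonds
#' is_mol_graph(parse_smiles("not_a_smiles"))
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  sdf <- tryCatch(
    .ob_convert("SMI", "SDF", paste0(smiles, "\n")),
    error = function(e) ""
  )
  recs <- .molfile_records(sdf)
  parsed <- if (length(recs) >= 1L) .read_v2000(recs[[1L]]) else NULL
  if (is.null(parsed)) {
    return(structure(list(smiles = smiles, reason = "unparseable SMILES"),
                     class = "smiles_parse_failure"))
  }
  atom_type <- match(parsed$element, .ELEMENTS)
  if (anyNA(atom_type)) {
    return(structure(list(smiles = smiles, reason = "unknown element symbol"),
                     class = "smiles_parse_failure"))
  }
  chir <- parsed$parity
  chir[!(chir %in% 0:2)] <- 3L
  bonds <- if (is.null(parsed$bonds)) {
    data.frame(i = integer(0), j = integer(0), type = integer(0),
               dir = integer(0))
  } else {
    b <- parsed$bonds
    ii <- pmin(b$i, b$j)
    jj <- pmax(b$i, b$j)
    data.frame(i = ii, j = jj, type = .bond_type_code(b$order),
               dir = .bond_dir_code(b$stereo))
  }
  structure(
    list(
      n_atoms = parsed$natoms,
      element = parsed$element,
      atom_type = as.integer(atom_type),
      chirality = as.integer(chir) + 1L, # 1-based category codes
      bonds = bonds,
      smiles = smiles
    ),
    class = "mol_graph"
  )
}

#' @rdname parse_smiles
#' @param x An object returned by [parse_smiles()].
#' @export
is_mol_graph <- function(x) inherits(x, "mol_graph")

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms, %d bonds: %s\n",
              x$n_atoms, nrow(x$bonds), x$smiles))
  invisible(x)
}

#' Keep only records whose SMILES parse
#'
#' Drug tables occasionally contain strings that no toolkit can convert to a
#' molecular graph; those records are excluded before modelling. Order of the
#' kept records is preserved.
#'
#' @param records A data frame with columns `drug_id` and `smiles` (or a list
#'   of `c(id, smiles)` pairs).
#' @return A list with `kept` (the parseable subset of `records`, plus a
#'   `graph` list-column of `mol_graph` objects) and `dropped` (character
#'   vector of excluded drug ids).
#' @export
filter_parseable <- function(records) {
  if (!is.data.frame(records)) {
    records <- data.frame(
      drug_id = vapply(records, `[[`, character(1), 1L),
      smiles = vapply(records, `[[`, character(1), 2L)
    )
  }
  stopifnot(all(c("drug_id", "smiles") %in% names(records)))
  graphs <- lapply(records$smiles, parse_smiles)
  ok <- vapply(graphs, is_mol_graph, logical(1))
  kept <- records[ok, , drop = FALSE]
  kept$graph <- graphs[ok]
  rownames(kept) <- NULL
  list(kept = kept, dropped = as.character(records$drug_id[!ok]))
}

# adjacency list over bonds of a mol_graph
.mol_adj_list <- function(g) {
  adj <- vector("list", g$n_atoms)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# hop distances from a source atom (BFS); unreachable = Inf
.mol_hops <- function(g, from) {
  dist <- rep(Inf, g$n_atoms)
  dist[from] <- 0
  adj <- .mol_adj_list(g)
  frontier <- from
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# induced subgraph on a set of atoms (re-indexed in the order given)
.mol_induce <- function(g, atoms) {
  atoms <- as.integer(atoms)
  keep <- g$bonds$i %in% atoms & g$bonds$j %in% atoms
  b <- g$bonds[keep, , drop = FALSE]
  remap <- match(seq_len(g$n_atoms), atoms)
  structure(
    list(
      n_atoms = length(atoms),
      element = g$element[atoms],
      atom_type = g$atom_type[atoms],
      chirality = g$chirality[atoms],
      bonds = data.frame(
        i = pmin(remap[b$i], remap[b$j]),
        j = pmax(remap[b$i], remap[b$j]),
        type = b$type, dir = b$dir
      ),
      smiles = g$smiles,
      parent_atoms = atoms
    ),
    class = "mol_graph"
  )
}

# serialize a mol_graph back to a minimal V2000 molfile (coordinates are not
# meaningful; OpenBabel only needs connectivity and elements downstream)
.mol_to_molfile <- function(g) {
  header <- c("", " mvddi", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    g$n_atoms, nrow(g$bonds))
  atoms <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    g$element
  )
  order <- ifelse(g$bonds$type %in% 1:4, g$bonds$type, 1L)
  bonds <- sprintf("%3d%3d%3d  0", g$bonds$i, g$bonds$j, order)
  paste0(paste(c(header, counts, atoms, bonds, "M  END", "$$$$"),
               collapse = "\n"), "\n")
}

# canonical SMILES of a mol_graph via OpenBabel
.mol_canonical_smiles <- function(g) {
  out <- tryCatch(.ob_convert("SDF", "CAN", .mol_to_molfile(g)),
                  error = function(e) "")
  out <- strsplit(out, "[\t\n]")[[1]]
  if (length(out) == 0L) "" else trimws(out[[1L]])
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Reduces a molecule to its scaffold — the ring systems plus the linker
#' atoms connecting them — by iteratively deleting terminal atoms attached
#' through single bonds. Terminal atoms held by higher-order bonds (e.g. an
#' exocyclic carbonyl oxygen) are retained, matching the usual toolkit
#' convention. The scaffold is returned as a canonical SMILES string so that
#' structurally identical frameworks compare equal; acyclic molecules have no
#' scaffold and map to the empty string.
#'
#' @param smiles A SMILES string.
#' @return The canonical scaffold SMILES (`""` for acyclic molecules), or a
#'   `smiles_parse_failure` object when the input does not parse.
#' @examples
#' bemis_murcko_scaffold("c1ccccc1")     # benzene is its own scaffold
#' bemis_murcko_scaffold("CCO")          # "" - no ring system
#' bemis_murcko_scaffold("CCc1ccccc1") == bemis_murcko_scaffold("c1ccccc1")
#' @export
bemis_murcko_scaffold <- function(smiles) {
  g <- if (is_mol_graph(smiles)) smiles else parse_smiles(smiles)
  if (!is_mol_graph(g)) return(g)
  bonds <- g$bonds
  # the 2-core of the bond graph: iteratively strip terminal atoms; what
  # survives is exactly the ring systems plus the linkers between them
  keep <- rep(TRUE, g$n_atoms)
  repeat {
    live <- bonds[keep[bonds$i] & keep[bonds$j], , drop = FALSE]
    deg <- tabulate(c(live$i, live$j), nbins = g$n_atoms)
    drop <- keep & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  if (!any(keep)) return("")
  # re-attach atoms held to the framework by a double/triple bond (e.g. an
  # exocyclic carbonyl oxygen), per the usual scaffold convention
  multi <- bonds$type %in% c(2L, 3L)
  attach <- (keep[bonds$i] & !keep[bonds$j] & multi) |
    (!keep[bonds$i] & keep[bonds$j] & multi)
  keep[c(bonds$i[attach], bonds$j[attach])] <- TRUE
  .mol_canonical_smiles(.mol_induce(g, which(keep)))
}
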