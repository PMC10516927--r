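#' Load an atomic structure model
#'
#' Parses PDB or mmCIF coordinates (via bio3d) into a flat atom table.  The
#' first model of multi-model files is used, alternate locations are resolved
#' to the highest-occupancy conformer, and waters are excluded by default.
#'
#' @param path `.pdb`/`.ent` or `.cif` file.
#' @param keep_waters retain water molecules (default `FALSE`).
#' @return object of class `structure_model`: list with `atoms` (data.frame
#'   `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`, `o`) and `path`.
#' @export
load_structure <- function(path, keep_waters = FALSE) {
  .assert(file.exists(path), "file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
         else bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!keep_waters) at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), ,
                             drop = FALSE]
  ## resolve altlocs: keep the highest-occupancy conformer per atom
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$elety, sep = "|")
    ord <- order(key, -occ, alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$elety, sep = "|")), ,
             drop = FALSE]
    at <- at[order(at$chain, at$resno), , drop = FALSE]
  }
  .assert(all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z)),
          "non-finite coordinates in %s", path)
  atoms <- data.frame(chain = as.character(at$chain),
                      resno = as.integer(at$resno),
                      resid = as.character(at$resid),
                      elety = as.character(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      o = if (is.null(at$o)) 1 else at$o,
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, path = path), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, chains: %s\n", nrow(x$atoms),
              paste(sort(unique(x$atoms$chain)), collapse = " ")))
  invisible(x)
}

.get_atom <- function(model, chain, resno, elety = "CA") {
  a <- model$atoms
  hit <- a[a$chain == chain & a$resno == resno & a$elety == elety, ,
           drop = FALSE]
  .assert(nrow(hit) >= 1, "missing %s atom for chain %s residue %d",
          elety, chain, as.integer(resno))
  unlist(hit[1, c("x", "y", "z")])
}

#' C-alpha distance between two residues
#'
#' Euclidean distance between the CA atoms of residues `a` and `b`;
#' symmetric in argument order.
#'
#' @param model a [load_structure()] model.
#' @param a,b residue addresses, each `list(chain, resno)` or a length-2
#'   vector `c(chain, resno)`.
#' @return list of class `distance_result`: `a`, `b`, `atom_pair`
#'   (`"CA-CA"`), `distance` (Å).
#' @export
ca_distance <- function(model, a, b) {
  pa <- .get_atom(model, as.character(a[[1]]), as.integer(a[[2]]))
  pb <- .get_atom(model, as.character(b[[1]]), as.integer(b[[2]]))
  structure(list(a = a, b = b, atom_pair = "CA-CA",
                 distance = sqrt(sum((pa - pb)^2))),
            class = "distance_result")
}

#' Scan a residue pair across all chain pairs
#'
#' For every ordered pair of distinct chains, reports the CA-CA distance
#' between residue `resnum_a` in the first chain and residue `resnum_b` in
#' the second; used to compare within-dimer against cross-dimer geometry.
#' Chain pairs lacking either residue are skipped.
#'
#' @param model a [load_structure()] model.
#' @param resnum_a,resnum_b residue numbers.
#' @return data.frame (`chain_a`, `chain_b`, `resno_a`, `resno_b`,
#'   `distance`) sorted ascending by distance.  A single-chain model yields
#'   an empty table with a warning.
#' @export
cross_chain_pair_scan <- function(model, resnum_a, resnum_b) {
  chains <- sort(unique(model$atoms$chain))
  empty <- data.frame(chain_a = character(), chain_b = character(),
                      resno_a = integer(), resno_b = integer(),
                      distance = numeric())
  if (length(chains) < 2) {
    warning("fewer than two chains: no cross-chain pairs")
    return(empty)
  }
  has <- function(ch, rn) {
    any(model$atoms$chain == ch & model$atoms$resno == rn &
          model$atoms$elety == "CA")
  }
  rows <- list()
  for (ca in chains) for (cb in chains) {
    if (ca == cb || !has(ca, resnum_a) || !has(cb, resnum_b)) next
    d <- ca_distance(model, list(ca, resnum_a), list(cb, resnum_b))$distance
    rows[[length(rows) + 1L]] <-
      data.frame(chain_a = ca, chain_b = cb,
                 resno_a = as.integer(resnum_a),
                 resno_b = as.integer(resnum_b), distance = d,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$distance), , drop = FALSE]
}

#' Disulfide compatibility of a C-alpha distance
#'
#' A residue pair can in principle be cross-linked by an engineered disulfide
#' when its CA-CA distance lies within 3.5-7.5 Å (inclusive).
#'
#' @param distance CA-CA distance(s) in Å, >= 0.
#' @return character vector, `"compatible"` or `"incompatible"`.
#' @export
disulfide_compatible <- function(distance) {
  .assert(all(distance >= 0), "distance must be >= 0")
  ifelse(distance >= 3.5 & distance <= 7.5, "compatible", "incompatible")
}

.basic_atoms <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))
.acidic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Detect salt bridges
#'
#' Reports a contact whenever any basic side-chain nitrogen (Lys NZ; Arg
#' NH1/NH2/NE) lies within `cutoff` of any acidic side-chain oxygen (Asp
#' OD1/OD2; Glu OE1/OE2), grouped per residue pair; intra-chain contacts are
#' flagged separately from inter-chain ones.
#'
#' @param model a [load_structure()] model.
#' @param cutoff distance cutoff in Å (default 4.0, the usual
#'   structural-biology convention for a salt bridge).
#' @return data.frame with one row per contacting residue pair:
#'   `chain_basic`, `resno_basic`, `resid_basic`, `chain_acidic`,
#'   `resno_acidic`, `resid_acidic`, `min_distance`, `n_atom_contacts`,
#'   `inter_chain`.
#' @export
find_salt_bridges <- function(model, cutoff = 4.0) {
  a <- model$atoms
  pick <- function(spec) {
    sel <- rep(FALSE, nrow(a))
    for (res in names(spec)) sel <- sel | (a$resid == res & a$elety %in% spec[[res]])
    a[sel, , drop = FALSE]
  }
  bas <- pick(.basic_atoms)
  aci <- pick(.acidic_atoms)
  empty <- data.frame(chain_basic = character(), resno_basic = integer(),
                      resid_basic = character(), chain_acidic = character(),
                      resno_acidic = integer(), resid_acidic = character(),
                      min_distance = numeric(), n_atom_contacts = integer(),
                      inter_chain = logical())
  if (!nrow(bas) || !nrow(aci)) return(empty)
  dx <- outer(bas$x, aci$x, "-")
  dy <- outer(bas$y, aci$y, "-")
  dz <- outer(bas$z, aci$z, "-")
  dm <- sqrt(dx^2 + dy^2 + dz^2)
  hits <- which(dm <= cutoff, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  contacts <- data.frame(
    chain_basic = bas$chain[hits[, 1]], resno_basic = bas$resno[hits[, 1]],
    resid_basic = bas$resid[hits[, 1]],
    chain_acidic = aci$chain[hits[, 2]], resno_acidic = aci$resno[hits[, 2]],
    resid_acidic = aci$resid[hits[, 2]],
    distance = dm[hits], stringsAsFactors = FALSE)
  key <- paste(contacts$chain_basic, contacts$resno_basic,
               contacts$chain_acidic, contacts$resno_acidic, sep = "|")
  agg <- lapply(split(contacts, key), function(g) {
    data.frame(chain_basic = g$chain_basic[1], resno_basic = g$resno_basic[1],
               resid_basic = g$resid_basic[1],
               chain_acidic = g$chain_acidic[1],
               resno_acidic = g$resno_acidic[1],
               resid_acidic = g$resid_acidic[1],
               min_distance = min(g$distance),
               n_atom_contacts = nrow(g),
               inter_chain = g$chain_basic[1] != g$chain_acidic[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$min_distance), , drop = FALSE]
}
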