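## Shared fixture builders and independent oracles.  Everything here is
## deliberately naive and separate from the package implementation paths.

## fragment set with prescribed lengths, laid head-to-tail on one element
frags_with_lengths <- function(lengths, gap = 10L, element_len = NULL) {
  starts <- cumsum(c(0L, utils::head(lengths + gap, -1)))
  elen <- element_len %||% (sum(lengths + gap) + gap)
  fragment_set(data.frame(element = "e1", start = starts,
                          end = starts + lengths),
               elements = c(e1 = as.integer(elen)), provenance = "test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## brute-force mean-removed autocorrelation (direct double loop)
oracle_autocorr <- function(counts, lags) {
  x <- as.numeric(counts) - mean(counts)
  denom <- sum(x^2)
  vapply(lags, function(l) {
    s <- 0
    for (t in seq_len(length(x) - l)) s <- s + x[t] * x[t + l]
    s / denom
  }, numeric(1))
}

## direct type-7 quantile (linear interpolation between order statistics)
oracle_quantile7 <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

## CDF of a Rayleigh(scale) truncated at cutoff
oracle_ptrunc_rayleigh <- function(q, scale, cutoff) {
  cap <- 1 - exp(-cutoff^2 / (2 * scale^2))
  pmin((1 - exp(-q^2 / (2 * scale^2))) / cap, 1)
}

## independent skew-normal sampler (delta representation)
oracle_rskewnorm <- function(n, xi, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  z1 <- abs(rnorm(n)); z2 <- rnorm(n)
  xi + omega * (delta * z1 + sqrt(1 - delta^2) * z2)
}

## minimal mmCIF rendering of a CA/side-chain geometry data.frame
write_fixture_cif <- function(geometry, path) {
  occ <- geometry$o
  if (is.null(occ)) occ <- rep(1, nrow(geometry))
  elem <- substr(gsub("[0-9]", "", geometry$elety), 1, 1)
  hdr <- c("data_synth", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.label_comp_id", "_atom_site.label_asym_id",
           "_atom_site.label_entity_id", "_atom_site.label_seq_id",
           "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
           "_atom_site.pdbx_PDB_model_num")
  rows <- sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 %d %s %s %s 1",
                  seq_len(nrow(geometry)), elem, geometry$elety,
                  geometry$resid, geometry$chain, geometry$resno,
                  geometry$x, geometry$y, geometry$z, occ,
                  geometry$resno, geometry$resid, geometry$chain,
                  geometry$elety)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

## random rigid-body transform applied to a geometry data.frame
rigid_transform <- function(geometry, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  R <- rx %*% ry %*% rz
  tr <- runif(3, -50, 50)
  xyz <- as.matrix(geometry[, c("x", "y", "z")]) %*% t(R)
  geometry$x <- xyz[, 1] + tr[1]
  geometry$y <- xyz[, 2] + tr[2]
  geometry$z <- xyz[, 3] + tr[3]
  geometry
}

## 4-chain tetramer-like fixture: K80 (NZ) and E95 (OE1/OE2) pairs across
## the dimer-dimer interface, CA atoms included, built from explicit
## coordinates so distances are hand-checkable
tetramer_fixture <- function() {
  ## within each facing pair the Lys NZ of one chain sits 3.0 A from the Glu
  ## OE1 of the other (two bridges per interface, four in total over the
  ## A-D and B-C interfaces), while intra-chain NZ-OE1 distances are 6 A
  left <- function(chain, oy) {
    data.frame(chain = chain, resno = c(80L, 80L, 95L, 95L),
               resid = c("LYS", "LYS", "GLU", "GLU"),
               elety = c("CA", "NZ", "CA", "OE1"),
               x = c(-1.5, 0, -1.5, 0), y = oy + c(0, 0, 6, 6), z = 0,
               stringsAsFactors = FALSE)
  }
  right <- function(chain, oy) {
    data.frame(chain = chain, resno = c(80L, 80L, 95L, 95L),
               resid = c("LYS", "LYS", "GLU", "GLU"),
               elety = c("CA", "NZ", "CA", "OE1"),
               x = c(4.5, 3, 4.5, 3), y = oy + c(6, 6, 0, 0), z = 0,
               stringsAsFactors = FALSE)
  }
  rbind(left("A", 0), right("D", 0), left("B", 20), right("C", 20))
}
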