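#' Write a minimal synthetic PDB-format coordinate file
#'
#' Emits fixed-width ATOM records for a constructed geometry so that
#' [load_structure()] round-trips chains, residues, atom names and
#' coordinates losslessly to 3 decimals.  Intended for synthetic test
#' fixtures, not for re-serialising experimental structures.
#'
#' @param geometry data.frame with columns `chain` (single alphanumeric
#'   character), `resno` (integer), `resid` (3-letter residue name), `elety`
#'   (atom name, <= 4 characters), `x`, `y`, `z` (Å); optional `o`
#'   (occupancy, default 1).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fixture_structure <- function(geometry, path) {
  .assert(is.data.frame(geometry) && nrow(geometry) > 0,
          "geometry must be a nonempty data.frame")
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  .assert(all(need %in% names(geometry)),
          "geometry needs columns %s", paste(need, collapse = ", "))
  .assert(all(is.finite(geometry$x) & is.finite(geometry$y) &
              is.finite(geometry$z)), "coordinates must be finite")
  .assert(all(grepl("^[A-Za-z0-9]$", geometry$chain)),
          "chain ids must be single alphanumeric characters")
  .assert(all(geometry$resno == as.integer(geometry$resno)) &&
          all(geometry$resno >= 0 & geometry$resno <= 9999),
          "residue numbers must be integers in 0..9999")
  .assert(all(nchar(geometry$elety) >= 1 & nchar(geometry$elety) <= 4),
          "atom names must be 1-4 characters")
  occ <- geometry$o %||% rep(1, nrow(geometry))
  ## PDB atom-name convention: 1-2 character element symbols start in
  ## column 14, so short names get a leading space
  name4 <- ifelse(nchar(geometry$elety) <= 3,
                  sprintf(" %-3s", geometry$elety),
                  sprintf("%-4s", geometry$elety))
  elem <- substr(gsub("[0-9]", "", geometry$elety), 1, 1)
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(geometry)), name4, geometry$resid, geometry$chain,
    as.integer(geometry$resno), geometry$x, geometry$y, geometry$z,
    occ, 0, elem)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Idealised C-alpha helix trace
#'
#' Ten-residue (by default) alpha-helical CA trace with exactly `spacing` Å
#' between consecutive CA atoms (rise 1.5 Å per residue, 100 degrees per
#' turn, radius solved from the chord length).  Used as a self-consistent
#' geometry fixture.
#'
#' @param n residues.
#' @param chain chain identifier.
#' @param spacing consecutive CA-CA distance in Å.
#' @return geometry data.frame suitable for [write_fixture_structure()].
#' @export
helix_ca_trace <- function(n = 10L, chain = "A", spacing = 3.8) {
  rise <- 1.5
  turn <- 100 * pi / 180
  chord <- sqrt(spacing^2 - rise^2)
  radius <- chord / (2 * sin(turn / 2))
  i <- seq_len(n) - 1L
  data.frame(chain = chain, resno = i + 1L, resid = "ALA", elety = "CA",
             x = radius * cos(i * turn), y = radius * sin(i * turn),
             z = rise * i, stringsAsFactors = FALSE)
}
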