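#' @include AllClasses.R
NULL

## charge-atom selection rule: NZ for Lys, CZ for Arg, CG for Asp,
## CD for Glu; His is not treated as charged
.CHARGE_ATOM <- c(LYS = "NZ", ARG = "CZ", ASP = "CG", GLU = "CD")
.CHARGE_SIGN <- c(LYS = 1, ARG = 1, ASP = -1, GLU = -1)

#' Charge atom name for a residue type
#'
#' @param resid three-letter residue name(s)
#' @return atom name(s): NZ (K), CZ (R), CG (D), CD (E)
#' @export
chargeAtom <- function(resid) unname(.CHARGE_ATOM[toupper(resid)])

#' Specification of a synthetic charged-residue bundle ensemble
#'
#' Describes charged sites (one charge atom per residue) and their
#' per-frame coordinates, as a stand-in for the charged residues of a
#' transmembrane four-helix bundle. Coordinates are quantized to
#' 0.001 Angstrom (PDB coordinate precision) at construction so that
#' writing and re-reading the ensemble as PDB is lossless.
#'
#' @param sites data.frame with columns chain, resno, resname
#'   (three-letter: LYS, ARG, ASP, GLU)
#' @param coords numeric array \code{[nSites, 3, nFrames]} of charge-atom
#'   coordinates, Angstrom
#' @param midplaneZ membrane midplane position, Angstrom
#' @return a list of class \code{"BundleSpec"}
#' @examples
#' sites <- data.frame(chain = "A", resno = c(1, 2),
#'                     resname = c("LYS", "ASP"))
#' co <- array(c(0, 0, 0, 3, 0, 0), dim = c(2, 3, 1))
#' spec <- bundleSpec(sites, co)
#' @export
bundleSpec <- function(sites, coords, midplaneZ = 0) {
  stopifnot(all(c("chain", "resno", "resname") %in% names(sites)))
  sites$resname <- toupper(sites$resname)
  if (!all(sites$resname %in% names(.CHARGE_ATOM)))
    stop("resname must be one of LYS, ARG, ASP, GLU")
  if (anyDuplicated(sites[c("chain", "resno")]))
    stop("clashing residue numbering: chain/resno pairs must be unique")
  if (length(dim(coords)) != 3 || dim(coords)[1] != nrow(sites) ||
      dim(coords)[2] != 3)
    stop("coords must be an [nSites, 3, nFrames] array")
  if (dim(coords)[3] < 1) stop("at least one frame required")
  structure(list(sites = sites,
                 coords = round(coords, 3),   # PDB precision
                 midplaneZ = midplaneZ),
            class = "BundleSpec")
}

#' Random bundle specification
#'
#' Charged sites drawn uniformly in a box, with independent per-frame
#' positions; a generic fixture for distance-map testing.
#'
#' @param nSites number of charged sites
#' @param nFrames number of frames
#' @param chains chain IDs to distribute sites over
#' @param box box half-widths (x, y, z), Angstrom
#' @param midplaneZ membrane midplane, Angstrom
#' @param seed RNG seed
#' @return a \code{"BundleSpec"}
#' @export
randomBundleSpec <- function(nSites = 20, nFrames = 5, chains = "A",
                             box = c(20, 20, 20), midplaneZ = 0,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chain <- rep(chains, length.out = nSites)
  resname <- sample(names(.CHARGE_ATOM), nSites, replace = TRUE)
  resno <- stats::ave(seq_len(nSites), chain, FUN = seq_along)
  co <- array(stats::runif(nSites * 3 * nFrames, -1, 1) *
                rep(box, each = nSites),
              dim = c(nSites, 3, nFrames))
  bundleSpec(data.frame(chain = chain, resno = resno, resname = resname),
             co, midplaneZ = midplaneZ)
}

#' Four-helix-bundle layout for charged sites
#'
#' Places each site near one of four helix axes arranged on a square of
#' the given radius, at a prescribed height z, and adds small Gaussian
#' positional jitter per frame (thermal motion stand-in). Emulates the
#' geometry of a transmembrane S1-S4 bundle with charges pointing
#' towards the bundle lumen.
#'
#' @param residues data.frame with columns chain, resno, resname, helix
#'   (1-4), z (Angstrom)
#' @param nFrames number of frames
#' @param radius distance of helix axes from the bundle axis, Angstrom
#' @param jitter per-frame positional sd, Angstrom
#' @param midplaneZ membrane midplane, Angstrom
#' @param seed RNG seed
#' @return a \code{"BundleSpec"}
#' @export
fourHelixBundle <- function(residues, nFrames = 5, radius = 8,
                            jitter = 0.2, midplaneZ = 0, seed = NULL) {
  stopifnot(all(c("chain", "resno", "resname", "helix", "z") %in%
                  names(residues)),
            all(residues$helix %in% 1:4))
  if (!is.null(seed)) set.seed(seed)
  ang <- (residues$helix - 1) * pi / 2 + pi / 4
  ## charges face the lumen: offset from the axis towards the center
  cx <- radius * cos(ang) * 0.7
  cy <- radius * sin(ang) * 0.7
  n <- nrow(residues)
  co <- array(NA_real_, dim = c(n, 3, nFrames))
  for (f in seq_len(nFrames)) {
    co[, 1, f] <- cx + stats::rnorm(n, 0, jitter)
    co[, 2, f] <- cy + stats::rnorm(n, 0, jitter)
    co[, 3, f] <- residues$z + stats::rnorm(n, 0, jitter)
  }
  bundleSpec(residues[c("chain", "resno", "resname")], co,
             midplaneZ = midplaneZ)
}

#' Realize a bundle specification as a coordinate ensemble
#'
#' @param spec a \code{"BundleSpec"}
#' @return a \linkS4class{StructureEnsemble} with one charge atom per
#'   site and the spec's coordinates (exact to PDB precision)
#' @examples
#' ens <- generateBundleEnsemble(randomBundleSpec(6, 2, seed = 1))
#' nFrames(ens)
#' @export
generateBundleEnsemble <- function(spec) {
  stopifnot(inherits(spec, "BundleSpec"))
  n <- nrow(spec$sites)
  nf <- dim(spec$coords)[3]
  atoms <- data.frame(chain = spec$sites$chain,
                      resno = spec$sites$resno,
                      resid = spec$sites$resname,
                      elety = chargeAtom(spec$sites$resname),
                      stringsAsFactors = FALSE)
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3 * n)
  for (f in seq_len(nf))
    xyz[f, ] <- as.vector(t(spec$coords[, , f]))
  new("StructureEnsemble", atoms = atoms, xyz = xyz,
      midplaneZ = spec$midplaneZ)
}

#' @rdname nFrames
#' @export
setMethod("nFrames", "StructureEnsemble", function(x) nrow(x@xyz))

#' Coordinates of one frame
#'
#' @param x a \linkS4class{StructureEnsemble}
#' @param frame frame index (1-based)
#' @return numeric matrix [nAtoms, 3]
#' @export
frameCoords <- function(x, frame = 1) {
  stopifnot(frame >= 1, frame <= nFrames(x))
  matrix(x@xyz[frame, ], ncol = 3, byrow = TRUE)
}

#' @rdname writeEnsemblePDB
#' @export
setMethod("writeEnsemblePDB", "StructureEnsemble", function(x, path, ...) {
  bio3d::write.pdb(file = path, xyz = x@xyz,
                   resno = x@atoms$resno, resid = x@atoms$resid,
                   eleno = seq_len(nrow(x@atoms)),
                   elety = x@atoms$elety, chain = x@atoms$chain)
  invisible(path)
})

#' Load a (multi-MODEL) PDB file as a StructureEnsemble
#'
#' @param path PDB file; MODEL/ENDMDL blocks become frames, a file
#'   without MODEL records is a single-frame ensemble
#' @param midplaneZ membrane midplane annotation, Angstrom
#' @return a \linkS4class{StructureEnsemble}
#' @export
loadEnsemble <- function(path, midplaneZ = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("malformed or empty PDB file: ",
                         conditionMessage(e)))
  if (is.null(pdb$xyz) || is.null(pdb$atom) || !nrow(pdb$atom) ||
      !nrow(as.matrix(pdb$xyz)) || !ncol(as.matrix(pdb$xyz)))
    stop("zero frames in PDB file")
  atoms <- pdb$atom[c("chain", "resno", "resid", "elety")]
  atoms$chain[is.na(atoms$chain)] <- "A"
  xyz <- matrix(as.numeric(pdb$xyz), nrow = nrow(as.matrix(pdb$xyz)))
  new("StructureEnsemble", atoms = atoms, xyz = xyz,
      midplaneZ = midplaneZ)
}

setMethod("show", "StructureEnsemble", function(object) {
  cat(sprintf("StructureEnsemble: %d atoms x %d frame(s), chains %s\n",
              nrow(object@atoms), nFrames(object),
              paste(unique(object@atoms$chain), collapse = ",")))
})
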