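#' @include bundle.R
NULL

#' Select charged sites from an ensemble
#'
#' One site per K/R/D/E residue possessing its designated charge atom
#' (NZ for Lys, CZ for Arg, CG for Asp, CD for Glu). Residues of a
#' charged type that lack the atom are reported in the \code{"missing"}
#' attribute and raised as a warning, never silently dropped. Histidine
#' is not treated as charged.
#'
#' @param ensemble a \linkS4class{StructureEnsemble}
#' @param residues residue types to consider
#' @return data.frame with columns chain, resno, resid, elety, sign,
#'   atom (index into the ensemble's atom table) and attribute
#'   \code{"missing"} (data.frame of charged residues lacking the atom)
#' @examples
#' ens <- generateBundleEnsemble(randomBundleSpec(6, 2, seed = 1))
#' selectChargedSites(ens)
#' @export
selectChargedSites <- function(ensemble,
                               residues = c("LYS", "ARG", "ASP", "GLU")) {
  at <- ensemble@atoms
  res <- unique(at[at$resid %in% residues, c("chain", "resno", "resid")])
  rows <- list(); miss <- list()
  for (i in seq_len(nrow(res))) {
    want <- chargeAtom(res$resid[i])
    j <- which(at$chain == res$chain[i] & at$resno == res$resno[i] &
                 at$resid == res$resid[i] & at$elety == want)
    if (length(j)) {
      rows[[length(rows) + 1]] <- cbind(res[i, , drop = FALSE],
                                        elety = want,
                                        sign = unname(.CHARGE_SIGN[res$resid[i]]),
                                        atom = j[1])
    } else {
      miss[[length(miss) + 1]] <- cbind(res[i, , drop = FALSE],
                                        missing_atom = want)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(chain = character(), resno = integer(),
                         resid = character(), elety = character(),
                         sign = numeric(), atom = integer())
  rownames(out) <- NULL
  missing <- if (length(miss)) do.call(rbind, miss)
             else data.frame(chain = character(), resno = integer(),
                             resid = character(),
                             missing_atom = character())
  rownames(missing) <- NULL
  if (nrow(missing))
    warning(nrow(missing), " charged residue(s) lack their charge atom; ",
            "see attr(, 'missing')")
  attr(out, "missing") <- missing
  out
}

.siteLabel <- function(sites) paste0(sites$resid, sites$resno)

## resolve a window argument to frame indices: a single double in (0, 1]
## is a trailing fraction (1 = all frames); an integer (or any vector)
## gives explicit frame indices
.resolveWindow <- function(window, nf) {
  if (is.null(window)) window <- 0.25
  if (length(window) == 1 && is.double(window) &&
      window > 0 && window <= 1) {
    k <- max(1L, ceiling(window * nf))
    return(seq(nf - k + 1L, nf))
  }
  idx <- as.integer(window)
  if (!length(idx) || any(idx < 1 | idx > nf))
    stop("window outside frame range 1..", nf)
  idx
}

#' Time-averaged acidic-basic charge-atom distance map
#'
#' For every (acidic, basic) pair of charged sites, the Euclidean
#' distance between charge atoms is averaged over the frames of the
#' window. The "last 20 ns" convention of trajectory analyses is
#' generalized to a trailing-fraction window (default: last 25 percent
#' of frames) since the frame-to-time mapping is metadata, not
#' geometry. Subunits are distinguished by chain ID and, under
#' \code{pairing = "within-chain"}, mapped separately — no symmetry
#' between chains is assumed.
#'
#' @param ensemble a \linkS4class{StructureEnsemble}
#' @param sites charged-site table from \code{\link{selectChargedSites}}
#'   (computed if \code{NULL})
#' @param window trailing fraction in (0, 1] or integer frame indices;
#'   \code{NULL} = last 25 percent
#' @param pairing "within-chain" (one matrix per chain) or "all"
#' @return a \linkS4class{DistanceMap}
#' @examples
#' ens <- generateBundleEnsemble(randomBundleSpec(8, 4, seed = 2))
#' meanDistanceMap(ens, window = 1)   # all frames
#' @export
meanDistanceMap <- function(ensemble, sites = NULL, window = NULL,
                            pairing = c("within-chain", "all")) {
  pairing <- match.arg(pairing)
  if (is.null(sites))
    sites <- suppressWarnings(selectChargedSites(ensemble))
  frames <- .resolveWindow(window, nFrames(ensemble))
  coords <- lapply(frames, function(f) frameCoords(ensemble, f))
  oneMap <- function(sub) {
    neg <- sub[sub$sign < 0, , drop = FALSE]
    pos <- sub[sub$sign > 0, , drop = FALSE]
    m <- matrix(0, nrow(neg), nrow(pos),
                dimnames = list(.siteLabel(neg), .siteLabel(pos)))
    if (!nrow(neg) || !nrow(pos)) return(m)
    for (co in coords) {
      dn <- co[neg$atom, , drop = FALSE]
      dp <- co[pos$atom, , drop = FALSE]
      for (a in seq_len(nrow(neg)))
        m[a, ] <- m[a, ] + sqrt(colSums((t(dp) - dn[a, ])^2))
    }
    m / length(coords)
  }
  maps <- if (pairing == "within-chain")
    lapply(split(sites, sites$chain), oneMap)
  else list(all = oneMap(sites))
  new("DistanceMap", maps = maps, pairing = pairing,
      frames = as.integer(frames), nFrames = length(frames),
      sites = sites)
}

setMethod("show", "DistanceMap", function(object) {
  cat(sprintf("DistanceMap (%s): %d matrix/matrices, %d frame(s) averaged\n",
              object@pairing, length(object@maps), object@nFrames))
  for (nm in names(object@maps))
    cat(sprintf("  %s: %d acidic x %d basic\n", nm,
                nrow(object@maps[[nm]]), ncol(object@maps[[nm]])))
})

#' Distance map in long format
#'
#' @param map a \linkS4class{DistanceMap}
#' @return data.frame with columns chain, res_neg, res_pos,
#'   mean_distance_A, n_frames
#' @export
distanceMapTable <- function(map) {
  out <- do.call(rbind, lapply(names(map@maps), function(ch) {
    m <- map@maps[[ch]]
    if (!length(m)) return(NULL)
    expand <- expand.grid(res_neg = rownames(m), res_pos = colnames(m),
                          stringsAsFactors = FALSE)
    cbind(chain = ch, expand, mean_distance_A = as.vector(m),
          n_frames = map@nFrames)
  }))
  if (is.null(out))
    out <- data.frame(chain = character(), res_neg = character(),
                      res_pos = character(), mean_distance_A = numeric(),
                      n_frames = integer())
  rownames(out) <- NULL
  out
}

#' Call salt bridges from a distance map
#'
#' All (acidic, basic) pairs with mean charge-atom distance at or below
#' the cutoff (closed threshold), sorted by distance with deterministic
#' ties broken by chain and residue numbers. 4 Angstrom between charge
#' atoms is the common structural-biology convention; the full map is
#' available regardless, so the cutoff affects calling only.
#'
#' @param map a \linkS4class{DistanceMap}
#' @param cutoff distance cutoff, Angstrom (> 0)
#' @return data.frame: chain, res_neg, res_pos, mean_distance_A
#' @export
detectSaltBridges <- function(map, cutoff = 4.0) {
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  tab <- distanceMapTable(map)
  hit <- tab[tab$mean_distance_A <= cutoff, , drop = FALSE]
  num <- function(s) as.integer(sub("^[A-Z]+", "", s))
  o <- order(hit$mean_distance_A, hit$chain, num(hit$res_neg),
             num(hit$res_pos))
  out <- hit[o, c("chain", "res_neg", "res_pos", "mean_distance_A")]
  rownames(out) <- NULL
  out
}

#' Partition charged sites into salt-bridge clusters
#'
#' Connected components of the salt-bridge graph (vertices: all charged
#' sites; edges: called bridges). Each component is labeled
#' extracellular or intracellular by the mean z of its members relative
#' to the membrane midplane (z averaged over all frames). Sites with no
#' bridge form singleton clusters.
#'
#' @param bridges data.frame from \code{\link{detectSaltBridges}}
#' @param sites charged-site table from \code{\link{selectChargedSites}}
#' @param ensemble the \linkS4class{StructureEnsemble} the sites came
#'   from (for z coordinates)
#' @param midplaneZ membrane midplane, Angstrom (default: the
#'   ensemble's annotation)
#' @return data.frame: chain, resno, resid, site, cluster (integer id),
#'   label ("extracellular"/"intracellular"), cluster_mean_z
#' @export
partitionClusters <- function(bridges, sites, ensemble,
                              midplaneZ = NULL) {
  if (is.null(midplaneZ)) midplaneZ <- ensemble@midplaneZ
  if (!is.finite(midplaneZ)) midplaneZ <- 0
  key <- paste(sites$chain, .siteLabel(sites), sep = ":")
  g <- igraph::make_empty_graph(n = length(key), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = key)
  if (nrow(bridges)) {
    e1 <- match(paste(bridges$chain, bridges$res_neg, sep = ":"), key)
    e2 <- match(paste(bridges$chain, bridges$res_pos, sep = ":"), key)
    ok <- !is.na(e1) & !is.na(e2)
    g <- igraph::add_edges(g, rbind(e1[ok], e2[ok]))
  }
  comp <- igraph::components(g)$membership
  zmean <- vapply(seq_len(nrow(sites)), function(i)
    mean(ensemble@xyz[, 3 * (sites$atom[i] - 1) + 3]), numeric(1))
  czm <- tapply(zmean, comp, mean)
  data.frame(chain = sites$chain, resno = sites$resno,
             resid = sites$resid, site = .siteLabel(sites),
             cluster = as.integer(comp),
             label = ifelse(czm[as.character(comp)] >= midplaneZ,
                            "extracellular", "intracellular"),
             cluster_mean_z = unname(czm[as.character(comp)]))
}
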