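## Internal helpers shared across modules.

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

## "F387" for standard amino acids, "<resname><resid>" otherwise
residueId <- function(resname, resid) {
  one <- unname(AA3[resname])
  ifelse(is.na(one), paste0(resname, resid), paste0(one, resid))
}

isAminoAcid <- function(resname) resname %in% names(AA3)

#' Default residue-name to lipid-type mapping
#'
#' Maps common coarse-grained and atomistic residue names onto the lipid
#' types used throughout the package. Extend or override via the `lipidMap`
#' argument of [readStructure()].
#'
#' @return named character vector (residue name -> lipid type)
#' @export
defaultLipidMap <- function() {
  c(CHOL = "cholesterol", CHL1 = "cholesterol",
    POPC = "phospholipid", POPE = "phospholipid", DOPC = "phospholipid",
    DPPC = "phospholipid", POPS = "phospholipid", POPI = "phospholipid")
}

## designated head-particle names, in preference order, per lipid type
defaultHeadNames <- function() {
  list(cholesterol = c("ROH", "OH", "O3", "O1"),
       phospholipid = c("PO4", "P", "P8"))
}

## minimum-image component difference in an orthorhombic box
minImage <- function(dx, boxLen) dx - boxLen * round(dx / boxLen)

## per-frame minimum distance between two particle index sets;
## coords is [n_particles, 3, n_frames]
pairSetMinDist <- function(coords, box, idxA, idxB) {
  nf <- dim(coords)[3]
  best <- rep(Inf, nf)
  for (i in idxA) {
    xi <- coords[i, 1, ]; yi <- coords[i, 2, ]; zi <- coords[i, 3, ]
    for (j in idxB) {
      dx <- minImage(xi - coords[j, 1, ], box[1])
      dy <- minImage(yi - coords[j, 2, ], box[2])
      dz <- minImage(zi - coords[j, 3, ], box[3])
      best <- pmin(best, dx * dx + dy * dy + dz * dz)
    }
  }
  sqrt(best)
}

## Kabsch superposition: rotation R and translation so that R %*% (p - cp) + cq
## maps P (n x 3) onto Q (n x 3) in the least-squares sense
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(tcrossprod(s$v, s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(R = R, centerP = cp, centerQ = cq)
}

applyKabsch <- function(fit, X) {
  sweep(sweep(X, 2, fit$centerP) %*% t(fit$R), 2, fit$centerQ, "+")
}

## maximal runs of TRUE in a logical vector -> data.frame(start, length)
trueRuns <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], length = r$lengths[keep])
}

## deterministic seed derivation, kept below 2^31; every product stays well
## under 2^53 so the arithmetic is exact in doubles
deriveSeed <- function(seed, offset) {
  a <- as.numeric(seed) %% 2147483647
  b <- as.numeric(offset) %% 2147483647
  v <- (a * 48271) %% 2147483647
  v <- (v + (b * 69621) %% 2147483647) %% 2147483647
  v <- (v * 16807) %% 2147483647
  as.integer(if (v == 0) 1 else v)
}

## trapezoidal area under y(x)
trapz <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
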