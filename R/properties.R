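# Physical protein properties: length, average molecular weight,
# isoelectric point by charge bisection.

# Average (not monoisotopic) residue masses, Da.
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

#' Dissociation constants used for isoelectric-point computation
#'
#' Two classic pKa tables are shipped; both treat the termini and the seven
#' ionizable side chains (Asp, Glu, Cys, Tyr, His, Lys, Arg).
#' `"emboss"` (default) is the set used by the EMBOSS `iep` tool;
#' `"bjellqvist"` is the Expasy-style set with a flat N-terminal pKa.
#' Any named numeric vector with elements `nterm`, `cterm`, `C`, `D`, `E`,
#' `H`, `K`, `R`, `Y` can be substituted.
#'
#' @param set `"emboss"` or `"bjellqvist"`.
#' @return named numeric vector of pKa values.
#' @export
wrky_pka <- function(set = c("emboss", "bjellqvist")) {
  set <- match.arg(set)
  switch(set,
    emboss = c(nterm = 8.6, cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
               H = 6.5, K = 10.8, R = 12.5, Y = 10.1),
    bjellqvist = c(nterm = 7.5, cterm = 3.55, C = 9.0, D = 4.05, E = 4.45,
                   H = 5.98, K = 10.0, R = 12.0, Y = 10.0))
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water. `X` residues are rejected
#' by default; supply `x_mass` to assign them an average mass instead.
#'
#' @param seq protein string.
#' @param x_mass optional mass (Da) to use for `X` residues.
#' @return mass in daltons.
#' @export
#' @examples
#' molecular_weight("G")   # 75.07 Da
molecular_weight <- function(seq, x_mass = NULL) {
  chars <- check_protein(seq, allow_x = TRUE)
  if (!length(chars)) stop("empty sequence", call. = FALSE)
  if (any(chars == "X") && is.null(x_mass)) {
    stop("sequence contains X; supply x_mass to accept unknown residues",
         call. = FALSE)
  }
  masses <- AA_MASS[chars]
  masses[chars == "X"] <- x_mass
  sum(masses) + WATER_MASS
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the free termini and the ionizable side
#' chains (D, E, C, Y negative; H, K, R positive). Composition-only: the
#' result is invariant to residue order.
#'
#' @param seq protein string.
#' @param pH pH value (may be a vector).
#' @param pka pKa table, see [wrky_pka()].
#' @return net charge at each `pH`.
#' @export
net_charge <- function(seq, pH, pka = wrky_pka()) {
  chars <- check_protein(seq, allow_x = TRUE)
  if (!length(chars)) stop("empty sequence", call. = FALSE)
  counts <- table(factor(chars, levels = c(AA20, "X")))
  pos_frac <- function(pk) 1 / (1 + 10^(pH - pk))
  neg_frac <- function(pk) -1 / (1 + 10^(pk - pH))
  ch <- pos_frac(pka[["nterm"]]) + neg_frac(pka[["cterm"]])
  for (aa in c("H", "K", "R")) ch <- ch + counts[[aa]] * pos_frac(pka[[aa]])
  for (aa in c("D", "E", "C", "Y")) ch <- ch + counts[[aa]] * neg_frac(pka[[aa]])
  ch
}

#' Isoelectric point by bisection
#'
#' Finds the pH in [0, 14] at which [net_charge()] crosses zero, by
#' bisection to `|charge| < tol`. Net charge is strictly decreasing in pH,
#' so the root is unique.
#'
#' @param seq protein string.
#' @param pka pKa table, see [wrky_pka()].
#' @param tol charge tolerance terminating the bisection.
#' @return isoelectric point (pH units).
#' @export
#' @examples
#' isoelectric_point("KKKK") > isoelectric_point("DDDD")
isoelectric_point <- function(seq, pka = wrky_pka(), tol = 1e-4) {
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    ch <- net_charge(seq, mid, pka)
    if (abs(ch) < tol) break
    if (ch > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Physical property table for a set of proteins
#'
#' @param seqs named character vector of protein sequences.
#' @param pka pKa table for the isoelectric point.
#' @return data.frame with `id`, `length_aa`, `mw_da`, `mw_kda` (1 decimal,
#'   mirroring the catalog's published column), `pi`.
#' @export
protein_properties <- function(seqs, pka = wrky_pka()) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  data.frame(
    id = names(seqs),
    length_aa = nchar(seqs),
    mw_da = vapply(seqs, molecular_weight, numeric(1)),
    mw_kda = round(vapply(seqs, molecular_weight, numeric(1)) / 1000, 1),
    pi = vapply(seqs, isoelectric_point, numeric(1), pka = pka),
    row.names = NULL, stringsAsFactors = FALSE)
}
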