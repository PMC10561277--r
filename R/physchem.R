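# Average (isotope-weighted) residue masses, Da; water 18.0153 added once
# per chain.
.residue_mass <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.water_mass <- 18.0153

# pKa set used for theoretical pI (EMBOSS-style constants).
.pka <- list(
  nterm = 8.6, cterm = 3.6,
  K = 10.8, R = 12.5, H = 6.5,        # basic side chains
  D = 3.9, E = 4.1, C = 8.5, Y = 10.1 # acidic side chains
)

check_protein <- function(seq) {
  if (length(seq) != 1 || is.na(seq) || nchar(seq) == 0) {
    stop("sequence must be a non-empty string")
  }
  aa <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(aa), names(.residue_mass))
  if (length(bad) > 0) {
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  }
  aa
}

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water mass (18.0153 Da).
#' Additive up to water: `mw(ab) = mw(a) + mw(b) - 18.0153`.
#'
#' @param seq Amino-acid string over the standard 20 residues.
#' @return Molecular weight in Daltons.
#' @export
molecular_weight <- function(seq) {
  aa <- check_protein(seq)
  sum(.residue_mass[aa]) + .water_mass
}

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable side chains plus both termini:
#' basic groups contribute `1/(1 + 10^(pH - pKa))`, acidic groups
#' `-1/(1 + 10^(pKa - pH))`. Strictly decreasing in pH.
#'
#' @param seq Amino-acid string.
#' @param ph pH value(s).
#' @return Net charge (vectorized over `ph`).
#' @export
net_charge <- function(seq, ph) {
  aa <- check_protein(seq)
  counts <- table(aa)
  nres <- function(r) if (r %in% names(counts)) as.numeric(counts[[r]]) else 0
  pos_pka <- c(.pka$nterm, rep(.pka$K, nres("K")), rep(.pka$R, nres("R")),
               rep(.pka$H, nres("H")))
  neg_pka <- c(.pka$cterm, rep(.pka$D, nres("D")), rep(.pka$E, nres("E")),
               rep(.pka$C, nres("C")), rep(.pka$Y, nres("Y")))
  vapply(ph, function(p) {
    sum(1 / (1 + 10^(p - pos_pka))) - sum(1 / (1 + 10^(neg_pka - p)))
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' The pH at which [net_charge()] crosses zero, found by bisection on
#' [0, 14] to |charge| < `tol`. The charge function is strictly decreasing
#' in pH, so the root is unique; the termini guarantee at least one basic
#' and one acidic group, so a crossing always exists.
#'
#' @param seq Amino-acid string.
#' @param tol Charge tolerance at the returned pH.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, tol = 1e-4) {
  check_protein(seq)
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical profile of a protein set
#'
#' @param seqs Named character vector of protein sequences.
#' @return data.frame: protein_id, length_aa, mw_da, pi.
#' @export
physchem_profile <- function(seqs) {
  data.frame(
    protein_id = names(seqs),
    length_aa = nchar(seqs),
    mw_da = vapply(seqs, molecular_weight, numeric(1), USE.NAMES = FALSE),
    pi = vapply(seqs, isoelectric_point, numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Correlation between lineage median pI and optimal growth pH
#'
#' Pairs lineages by name and reports the Pearson correlation between the
#' median isoelectric point of a NAP family and the lineage's optimal
#' growth pH. When `acidophile_cutoff` is given, correlations are also
#' reported separately for lineages below (acidophile-like) and at/above
#' the cutoff, when each side has at least three lineages.
#'
#' @param lineage_median_pi Named numeric: median family pI per lineage.
#' @param optimal_ph Named numeric: optimal growth pH per lineage.
#' @param acidophile_cutoff Optional pH cut-point for the split.
#' @return List with elements `overall` (a `correlation_result`) and,
#'   when a cutoff is given, `below` and `at_or_above` (each a
#'   `correlation_result` or NULL when underpowered).
#' @export
pi_ph_correlation <- function(lineage_median_pi, optimal_ph,
                              acidophile_cutoff = NULL) {
  shared <- intersect(names(lineage_median_pi), names(optimal_ph))
  if (length(shared) < 3) stop("need at least 3 lineages with both values")
  pi_v <- lineage_median_pi[shared]
  ph_v <- optimal_ph[shared]
  res <- list(overall = pearson(ph_v, pi_v, "optimal_growth_ph",
                                "median_pi"))
  if (!is.null(acidophile_cutoff)) {
    grp <- function(sel) {
      if (sum(sel) >= 3 && stats::sd(ph_v[sel]) > 0 &&
          stats::sd(pi_v[sel]) > 0) {
        pearson(ph_v[sel], pi_v[sel], "optimal_growth_ph", "median_pi")
      } else NULL
    }
    res$below <- grp(ph_v < acidophile_cutoff)
    res$at_or_above <- grp(ph_v >= acidophile_cutoff)
  }
  res
}
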