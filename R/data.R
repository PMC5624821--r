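#' @keywords internal
#' @aliases relkit-package
"_PACKAGE"

#' Published reference statistics for five HGDP-CEPH Maya pairs
#'
#' IBS and IBD summary statistics reported for five pairs of individuals
#' from the Maya sample of the HGDP-CEPH diversity panel (377
#' microsatellites): one pair per documented relationship. Useful as a
#' realistic external reference and for internal-consistency checks — the
#' printed mean, sd and proportions of any pair must satisfy
#' `mean = p1 + 2 p2` and `sd^2 = p1 + 4 p2 - mean^2` up to rounding.
#' Reproducing these exact values requires the full HGDP-CEPH genotype
#' download, which the package does not ship.
#'
#' @return A tibble with columns `relationship`, `mean`, `sd`, `p0`, `p1`,
#'   `p2`, `k0`, `k1`, `k2`.
#' @export
maya_reference_pairs <- function() {
  tibble::tribble(
    ~relationship, ~mean, ~sd,  ~p0,   ~p1,   ~p2,   ~k0,   ~k1,   ~k2,
    "PO",          1.34,  0.48, 0.002, 0.650, 0.348, 0.009, 0.991, 0.000,
    "FS",          1.32,  0.60, 0.073, 0.532, 0.395, 0.214, 0.617, 0.169,
    "HS",          1.09,  0.64, 0.160, 0.581, 0.259, 0.447, 0.553, 0.000,
    "FC",          1.00,  0.67, 0.225, 0.546, 0.229, 0.657, 0.343, 0.000,
    "UN",          0.86,  0.67, 0.308, 0.526, 0.166, 0.731, 0.269, 0.000
  )
}
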