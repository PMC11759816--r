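#!/usr/bin/env Rscript
# Stage 8 (optional) - rerun stages 3-5 on the deposited otolith data.
#
# The published headline numbers (median shift ages, stage PERMANOVA, BIC grid,
# source proportions) depend on the deposited otolith measurements and the
# global seawater databases, which this repository does not bundle. If you have
# downloaded the deposited per-fish section data, point this driver at it:
#
#   Rscript analysis/08_deposited_data.R path/to/deposited_signatures.csv
#
# The file must provide one row per fish x region with columns fish_id, region
# (nuclear/marginal), event, the eight element:Ca ratios (Li, Na, Mg, Cr, Mn,
# Sr, Sn, Ba), d18O and d13C. Transect tables additionally enable the
# change-point stage through read_transects().

suppressMessages(library(otogeo))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !file.exists(args[1])) {
  cat("no deposited data supplied; skipping (see header for usage)\n")
  quit(save = "no", status = 0)
}
sig <- read.csv(args[1])
els <- intersect(c("Li", "Na", "Mg", "Cr", "Mn", "Sr", "Sn", "Ba"), names(sig))

contrasts <- do.call(rbind, lapply(c(els, "d18O", "d13C"), function(v)
  paired_contrast(sig, v, group_by_event = "event" %in% names(sig))))
print(contrasts[, c("variable", "mean_juvenile", "mean_adult", "t_statistic",
                    "df", "p_value")], digits = 3, row.names = FALSE)

X <- transform_signatures(as.matrix(sig[stats::complete.cases(sig[, els]), els]),
                          "log_zscore")
pv <- permanova(mahalanobis_gram(X),
                sig$region[stats::complete.cases(sig[, els])],
                n_perm = 9999, seed = 1)
print(pv)

nuc <- sig[sig$region == "nuclear", ]
ok <- stats::complete.cases(nuc[, els])
tab <- bic_select(transform_signatures(as.matrix(nuc[ok, els]), "log_zscore"))
print(head(as.data.frame(tab), 6), digits = 4, row.names = FALSE)
best <- attr(tab, "best")
cat("proportions:", sprintf("%.2f", best$proportions), "\n")
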