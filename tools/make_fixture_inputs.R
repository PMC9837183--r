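# Writes the deterministic oracle inputs:
#  - fixtures/oracle_roi.csv: a small ADC ROI (x, y, z, value, mask)
#  - fixtures/icc_tables.csv: three 30x2 ratings tables (table, row, r1, r2)
library(vesica)
dir.create("tests/testthat/fixtures", recursive = TRUE, showWarnings = FALSE)

set.seed(20260924)
d <- c(14L, 13L, 8L)
spacing <- c(1.2, 1.5, 3.0)
cx <- c(7.1, 6.6, 4.3)
ax <- c(5.4, 4.9, 2.7)
xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
r2 <- outer(outer(((xs - cx[1]) / ax[1])^2, ((ys - cx[2]) / ax[2])^2, `+`),
            ((zs - cx[3]) / ax[3])^2, `+`)
mask <- r2 <= 1
mask[12:14, 6:7, 4] <- TRUE   # appendage -> irregular surface
mask[2, 10:12, 5:6] <- TRUE    # small lobe
vol <- array(0, d)
idx <- which(mask)
co <- arrayInd(idx, d)
vol[idx] <- 1.05 + 0.04 * co[, 1] / d[1] + 0.06 * sin(co[, 2] / 2) +
  0.05 * rnorm(length(idx))
df <- data.frame(x = co[, 1], y = co[, 2], z = co[, 3],
                 value = round(vol[idx], 6))
write.csv(df, "tests/testthat/fixtures/oracle_roi.csv", row.names = FALSE)
cat("ROI voxels:", nrow(df), "\n")

set.seed(77)
tabs <- do.call(rbind, lapply(1:3, function(t) {
  subj <- rnorm(30, 10, 3)
  data.frame(table = t, row = 1:30,
             r1 = round(subj + rnorm(30, 0, 1), 6),
             r2 = round(subj + 0.5 + rnorm(30, 0, 1.5), 6))
}))
write.csv(tabs, "tests/testthat/fixtures/icc_tables.csv", row.names = FALSE)
cat("wrote icc tables\n")
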