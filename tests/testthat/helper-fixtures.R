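# Shared fixtures, built in code at test time.

# K planted orthogonal-ish maps with a noisy copy per peak
noisy_peak_maps <- function(templates, copies, noise_sd, seed) {
  set.seed(seed)
  K <- nrow(templates$maps)
  C <- ncol(templates$maps)
  maps <- templates$maps[rep(seq_len(K), each = copies), , drop = FALSE]
  maps + matrix(rnorm(length(maps), sd = noise_sd), nrow(maps), C)
}

# best |spatial correlation| of each planted map against any recovered map
recovery_corrs <- function(recovered, planted) {
  vapply(seq_len(nrow(planted$maps)), function(i) {
    max(vapply(seq_len(nrow(recovered$maps)), function(j)
      spatial_correlation(recovered$maps[j, ], planted$maps[i, ]),
      numeric(1)))
  }, numeric(1))
}

# exhaustive best GEV over all 2-block partitions of <= 8 maps, independent
# of the clustering code path (dominant-eigenvector template per block)
best_two_partition_gev <- function(maps, gfp) {
  n <- nrow(maps)
  stopifnot(n <= 8)
  maps <- maps - rowMeans(maps)
  maps <- maps / sqrt(rowSums(maps^2))
  block_gev <- function(idx) {
    tmpl <- eigen(crossprod(maps[idx, , drop = FALSE]),
                  symmetric = TRUE)$vectors[, 1]
    sum((gfp[idx] * abs(maps[idx, , drop = FALSE] %*% tmpl))^2)
  }
  best <- -Inf
  for (mask in 1:(2^n - 2)) {
    grp <- as.integer(intToBits(mask))[seq_len(n)]
    gv <- block_gev(which(grp == 1)) + block_gev(which(grp == 0))
    best <- max(best, gv / sum(gfp^2))
  }
  best
}

# write a minimal EDF file byte-by-byte from the format definition,
# independent of the package's EDF code (one 1-second record per call unit)
write_edf_fixture <- function(path, data, fs, labels,
                              phys_range = ceiling(max(abs(data)))) {
  C <- nrow(data); n <- ncol(data)
  stopifnot(n %% fs == 0)
  n_rec <- n %/% fs
  fld <- function(x, w) formatC(substr(as.character(x), 1, w), width = -w)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(fld("0", 8), fld("fixture", 80), fld("", 80),
                fld("02.02.20", 8), fld("12.00.00", 8),
                fld(256 * (1 + C), 8), fld("", 44), fld(n_rec, 8),
                fld(1, 8), fld(C, 4))
  writeChar(hdr, con, eos = NULL)
  per_sig <- list(list(labels, 16), list(rep("", C), 80),
                  list(rep("uV", C), 8),
                  list(rep(formatC(-phys_range, format = "g"), C), 8),
                  list(rep(formatC(phys_range, format = "g"), C), 8),
                  list(rep("-32767", C), 8), list(rep("32767", C), 8),
                  list(rep("", C), 80), list(rep(fs, C), 8),
                  list(rep("", C), 32))
  for (f in per_sig) for (v in f[[1]]) writeChar(fld(v, f[[2]]), con, eos = NULL)
  dig <- round(data / phys_range * 32767)
  for (r in seq_len(n_rec)) for (c_i in seq_len(C))
    writeBin(as.integer(dig[c_i, ((r - 1) * fs + 1):(r * fs)]),
             con, size = 2, endian = "little")
  invisible(path)
}

# write a BrainVision triplet (.vhdr + float32 multiplexed .eeg) byte-by-byte
write_brainvision_fixture <- function(stem, data, fs, labels) {
  vhdr <- paste0(stem, ".vhdr")
  eeg <- paste0(stem, ".eeg")
  C <- nrow(data)
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", basename(eeg)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", C),
    paste0("SamplingInterval=", format(1e6 / fs)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_len(C), labels)), vhdr)
  con <- file(eeg, "wb")
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  close(con)
  vhdr
}
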