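# shared fixture builders and independent oracles

# minimal cell table with all canonical columns; marker raw signals default 0
make_cells <- function(n = 3, core_id = "spot_001",
                       x = seq_len(n) * 10, y = rep(0, n),
                       perimeter = 150, cell_area = 700, nuclear_area = 80,
                       qc_pass = TRUE, ...) {
  cells <- data.frame(core_id = core_id,
                      cell_id = sprintf("c%03d", seq_len(n)),
                      centroid_x = x, centroid_y = y,
                      perimeter_px = rep_len(perimeter, n),
                      cell_area_px = rep_len(cell_area, n),
                      nuclear_area_px = rep_len(nuclear_area, n),
                      qc_pass = rep_len(qc_pass, n),
                      stringsAsFactors = FALSE)
  for (m in mxif_markers()) cells[[paste0("raw_", m)]] <- 0
  extra <- list(...)
  for (nm in names(extra)) cells[[nm]] <- rep_len(extra[[nm]], n)
  cells
}

# one-row core metadata with sane defaults (LumA-like scores)
make_meta <- function(core_id = "spot_001", case_id = "case_001",
                      er = 90, eri = "strong", pr = 80, pri = "strong",
                      her2 = "0", fish = NA_character_, ki67 = 10,
                      p53 = "normal", p16 = "normal", subtype = NULL) {
  m <- data.frame(core_id = core_id, case_id = case_id, pair_id = case_id,
                  ihc_er_percent = er, ihc_er_intensity = eri,
                  ihc_pr_percent = pr, ihc_pr_intensity = pri,
                  ihc_her2 = her2, fish_result = fish,
                  ihc_ki67_percent = ki67, ihc_p53 = p53, ihc_p16 = p16,
                  stringsAsFactors = FALSE)
  if (!is.null(subtype)) m$subtype <- subtype
  m
}

square_region <- function(x0, y0, x1, y1, label = "exclude_benign",
                          core_id = "spot_001") {
  structure(list(list(label = label, core_id = core_id,
                      vertices = cbind(c(x0, x1, x1, x0),
                                       c(y0, y0, y1, y1)))),
            class = "region_set")
}

# O(n^2) all-pairs neighbor oracle
brute_neighbors <- function(x, y, radius) {
  n <- length(x)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  lapply(seq_len(n), function(i) {
    j <- which(d2[i, ] <= radius^2)
    sort(j[j != i])
  })
}

# direct-formula Shannon equitability oracle
eh_oracle <- function(counts, s = sum(counts > 0)) {
  if (s <= 1) return(0)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p)) / log(s)
}
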