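# Brute-force oracles, deliberately independent of the package internals:
# plain nested computations over all pairwise distances.

# k-nearest windows by exhaustive all-pairs sort; ties by ascending cell_id,
# center always first.
oracle_windows <- function(cells, window_size) {
  ids <- as.character(cells$cell_id)
  n <- nrow(cells)
  k <- min(window_size, n)
  lapply(seq_len(n), function(i) {
    d <- sqrt((cells$x_um - cells$x_um[i])^2 +
                (cells$y_um - cells$y_um[i])^2)
    df <- data.frame(id = ids[-i], d = d[-i])
    df <- df[order(df$d, df$id), ]
    c(ids[i], df$id[seq_len(k - 1)])
  })
}

# per-source-cell nearest-target distance by exhaustive scan
oracle_nearest <- function(cells, source_type, target_type,
                           exclude_self = TRUE) {
  src <- which(cells$cell_type == source_type)
  tgt <- which(cells$cell_type == target_type)
  vapply(src, function(i) {
    cand <- tgt
    if (exclude_self) cand <- setdiff(cand, i)
    if (length(cand) == 0) return(NA_real_)
    min(sqrt((cells$x_um[cand] - cells$x_um[i])^2 +
               (cells$y_um[cand] - cells$y_um[i])^2))
  }, numeric(1))
}

# two-group log-rank statistic from first principles (sum of O-E over event
# times, variance from the hypergeometric term)
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) # 1 or 2
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  (o_minus_e)^2 / v
}

# random spot generator for oracle-equivalence checks
random_spot <- function(n, seed, types = cell_type_vocabulary()) {
  set.seed(seed)
  tibble::tibble(
    cell_id = sprintf("c%04d", sample(seq_len(10 * n), n)),
    patient_id = "P1",
    spot_id = "s1",
    x_um = runif(n, 0, 1000),
    y_um = runif(n, 0, 1000),
    cell_type = factor(sample(types, n, replace = TRUE), levels = types)
  )
}

# minimal labeled multi-spot table with known geometry
grid_cells <- function(coords, types, spot_id = "s1") {
  tibble::tibble(
    cell_id = sprintf("c%02d", seq_len(nrow(coords))),
    patient_id = "P1",
    spot_id = spot_id,
    x_um = coords[, 1],
    y_um = coords[, 2],
    cell_type = factor(types, levels = cell_type_vocabulary())
  )
}
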