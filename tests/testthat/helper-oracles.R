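# Independent oracles used by the tests. Kept deliberately naive: these
# re-derive expected results by brute force, never by calling the package's
# own scanning/intersection code paths.

# Regex-based SSR scan: for each unit size, greedy backreference matches of
# whole-unit repeats, filtered by threshold and unit irreducibility, then the
# same published resolution rules (longest span wins, ties to smaller units;
# survivors within the interruption distance merge into compounds).
ssr_regex_oracle <- function(sequences,
                             min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L),
                             compound_max_gap = 100L) {
  reducible <- function(u) {
    k <- nchar(u)
    for (p in seq_len(k - 1L))
      if (k %% p == 0L && strrep(substr(u, 1L, p), k %/% p) == u)
        return(TRUE)
    FALSE
  }
  one <- function(id, s) {
    s <- toupper(s)
    cands <- list()
    for (k in seq_along(min_repeats)) {
      # zero-width lookahead: report a candidate at every position where a
      # whole-unit repeat begins, so no run is hidden by an earlier match
      pat <- sprintf("(?=(([ACGT]{%d})\\2+))", k)
      m <- gregexpr(pat, s, perl = TRUE)[[1L]]
      if (m[1L] == -1L) next
      lens <- attr(m, "capture.length")[, 1L]
      for (i in seq_along(m)) {
        reps <- lens[i] %/% k
        unit <- substr(s, m[i], m[i] + k - 1L)
        if (reps < min_repeats[k] || reducible(unit)) next
        cands[[length(cands) + 1L]] <- data.frame(
          unit = unit, k = k, reps = reps, start = as.integer(m[i]),
          end = as.integer(m[i]) + k * reps - 1L, stringsAsFactors = FALSE)
      }
    }
    if (!length(cands)) return(NULL)
    cand <- do.call(rbind, cands)
    cand <- cand[order(-(cand$end - cand$start + 1L), cand$k, cand$start), ]
    taken <- rep(FALSE, nrow(cand))
    blocked <- cbind(start = integer(0), end = integer(0))
    for (i in seq_len(nrow(cand))) {
      if (!any(cand$start[i] <= blocked[, "end"] &
               cand$end[i] >= blocked[, "start"])) {
        taken[i] <- TRUE
        blocked <- rbind(blocked, c(start = cand$start[i], end = cand$end[i]))
      }
    }
    cand <- cand[taken, , drop = FALSE]
    cand <- cand[order(cand$start), , drop = FALSE]
    rows <- list()
    i <- 1L
    while (i <= nrow(cand)) {
      j <- i
      while (j < nrow(cand) &&
             cand$start[j + 1L] - cand$end[j] - 1L <= compound_max_gap)
        j <- j + 1L
      if (i == j) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = id, motif = cand$unit[i], unit_size = cand$k[i],
          repeats = cand$reps[i], start = cand$start[i], end = cand$end[i],
          kind = "perfect", stringsAsFactors = FALSE)
      } else {
        parts <- vapply(i:j, function(m2) {
          gap <- if (m2 == i) "" else {
            g <- cand$start[m2] - cand$end[m2 - 1L] - 1L
            if (g > 0L) sprintf("-%d-", g) else ""
          }
          sprintf("%s(%s)%d", gap, cand$unit[m2], cand$reps[m2])
        }, character(1L))
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = id, motif = paste(parts, collapse = ""),
          unit_size = NA_integer_, repeats = NA_integer_,
          start = cand$start[i], end = cand$end[j], kind = "compound",
          stringsAsFactors = FALSE)
      }
      i <- j + 1L
    }
    do.call(rbind, rows)
  }
  out <- do.call(rbind, lapply(names(sequences), function(id)
    one(id, sequences[[id]])))
  if (is.null(out))
    out <- data.frame(seq_id = character(), motif = character(),
                      unit_size = integer(), repeats = integer(),
                      start = integer(), end = integer(), kind = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Naive gene-by-gene intersection of significant sets.
naive_consistent <- function(de_list) {
  universe <- de_list[[1L]]$gene_id
  keep <- character(0)
  for (g in universe) {
    in_all <- TRUE
    for (d in de_list) {
      row <- d[d$gene_id == g, ]
      if (!row$significant) { in_all <- FALSE; break }
    }
    if (in_all) keep <- c(keep, g)
  }
  sort(keep)
}

# Build a minimal de_result-like data.frame for the consistency logic.
fake_de <- function(universe, sig, direction = NULL) {
  d <- data.frame(gene_id = universe,
                  significant = universe %in% sig,
                  stringsAsFactors = FALSE)
  d$direction <- ifelse(d$significant,
                        if (is.null(direction)) "up_in_A"
                        else direction[match(universe, names(direction))],
                        "none")
  d
}

# Small site table built by hand: depths is a named list sample -> c(ref, alt)
# recycled across sites.
make_sites <- function(gene_id, pos, ref, alt, qual, qd, depths) {
  df <- data.frame(gene_id = gene_id, pos = pos, ref = ref, alt = alt,
                   qual = qual, qd = qd, stringsAsFactors = FALSE)
  n <- nrow(df)
  for (s in names(depths)) {
    d <- depths[[s]]
    if (is.null(dim(d))) d <- matrix(rep(d, n), ncol = 2, byrow = TRUE)
    df[[paste0("ref_", s)]] <- d[, 1L]
    df[[paste0("alt_", s)]] <- d[, 2L]
  }
  structure(df, samples = names(depths), class = c("site_table", "data.frame"))
}

# Expected IUPAC code for a true two-allele genotype string "A/G".
truth_iupac <- function(geno) {
  vapply(geno, function(g) {
    a <- sort(strsplit(g, "/", fixed = TRUE)[[1L]])
    if (a[1L] == a[2L]) a[1L]
    else unname(coldacc:::iupac_pair_codes[paste0(a[1L], a[2L])])
  }, character(1L), USE.NAMES = FALSE)
}
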