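# Shared fixtures. Everything is generated in code under fixed seeds;
# trained models used by several test files are built lazily and memoized
# so the suite trains each network once.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

random_guide_seq <- function(pam = "AGG") {
  paste0(paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
               collapse = ""), pam)
}

# independent brute-force PAM scan: materialize every window and apply the
# definition directly (no regex, no shared code with the scanner)
brute_pam_scan <- function(genome) {
  rc <- function(s) {
    vapply(strsplit(chartr("ACGT", "TGCA", s), ""), function(v) {
      paste(rev(v), collapse = "")
    }, character(1))
  }
  out <- list()
  for (chrom in sort(names(genome))) {
    s <- genome[[chrom]]
    L <- nchar(s)
    if (L < 23) next
    st <- seq_len(L - 22)                     # 1-based window starts
    win <- substring(s, st, st + 22L)
    clean <- !grepl("[^ACGT]", win)
    plus <- clean & substring(win, 22, 23) == "GG"
    minus <- clean & substring(win, 1, 2) == "CC"
    rows <- data.frame(
      chrom = chrom,
      start = c(st[plus], st[minus]) - 1L,
      strand = rep(c("+", "-"), c(sum(plus), sum(minus))),
      sequence23 = c(win[plus], rc(win[minus])),
      stringsAsFactors = FALSE)
    out[[chrom]] <- rows
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start, match(df$strand, c("+", "-"))), ]
  rownames(df) <- NULL
  df
}

# brute-force Hamming distance over positions 1-20
brute_hamming20 <- function(a, b) {
  av <- strsplit(substr(a, 1, 20), "")[[1]]
  bv <- strsplit(substr(b, 1, 20), "")[[1]]
  sum(av != bv)
}

# small labeled on-target simulation shared across net/interpret tests
ontarget_fixture <- function() {
  fixture("ontarget_sim_small", function() {
    gen_ontarget_set(random_planted_rule(seed = 11), n_guides = 1200,
                     seed = 12)
  })
}

# quick trained on-target classifier (scratch) for prediction-contract tests
ontarget_model_fixture <- function() {
  fixture("ontarget_model_small", function() {
    sim <- ontarget_fixture()
    cfg <- network_config(task = "classification", epochs = 4, seed = 5)
    train_ontarget(NULL, sim$x[1:800, , ], sim$records$binary_label[1:800],
                   cfg)
  })
}

offtarget_fixture <- function() {
  fixture("offtarget_sim_small", function() {
    gen_offtarget_set(n_pairs = 4000, seed = 21)
  })
}
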