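# compact row builder for domain hit tables
hit <- function(protein, family, start, end, p, clan = NA_character_,
                bitscore = -log2(p), pseq = p) {
  data.frame(protein_id = protein, family_id = family, clan_id = clan,
             env_start = start, env_end = end, bitscore = bitscore,
             p_domain = p, p_sequence = pseq)
}

hitTable <- function(...) do.call(rbind, list(...))

# brute-force q-value oracle: minimum estimated pFDR over all observed
# thresholds t >= p, with pFDR(t) = t * pi0 * N / #{p <= t}
qvalueOracle <- function(p, nTot, pi0 = 1) {
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min(vapply(ts, function(t) t * pi0 * nTot / sum(p <= t),
                      numeric(1))))
  }, numeric(1))
}

# random mixture stratum collections for the optimizer tests
randomStrata <- function(k, nRange = c(500, 2000)) {
  StratumCollection(lapply(seq_len(k), function(i)
    MixtureSpec(runif(1, 0.5, 0.95), runif(1, 0.1, 0.5),
                sample(nRange[1]:nRange[2], 1))))
}

# a small synthetic domtblout file (hmmsearch per-domain table, Z=domZ=1)
writeDomtbloutFixture <- function(path) {
  writeLines(c(
    "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------",
    "protA                -            250 Fam1                 PF00001.1    120   1.2e-09   45.3   0.1   1   1   2.0e-09   2.0e-09   44.1   0.1     1   118    10   130     8   132 0.95 test protein A",
    "protA                -            250 Fam2                 PF00002.2     80   3.0e-03   12.7   0.0   1   2   5.0e-03   8.0e-03   10.2   0.0     2    78   140   216   138   218 0.88 test protein A",
    "protB                -            400 Fam1                 PF00001.1    120   4.0e-06   33.0   0.2   1   1   6.0e-06   6.0e-06   32.1   0.2     1   120    55   175    50   180 0.91 another protein",
    ""), path)
}
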