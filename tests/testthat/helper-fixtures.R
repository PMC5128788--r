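# shared fixtures, built in code at test time

# random count vector with a rare tail (some zeros, singletons, doubletons)
randCounts <- function(seed, maxS = 40L, maxCount = 60L) {
  set.seed(seed)
  S <- sample(3:maxS, 1L)
  x <- c(sample(0:3, ceiling(S / 2), replace = TRUE),
         sample(1:maxCount, floor(S / 2), replace = TRUE))
  if (sum(x) == 0) x[1L] <- 1L
  sample(x)
}

# 3-sample, 3-taxon toy table used by the TAC enumeration oracle
toyTable <- function() {
  communityTable(matrix(c(5, 0, 0,
                          1, 2, 0,
                          0, 3, 4,
                          2, 0, 0), nrow = 4, byrow = TRUE,
                        dimnames = list(paste0("t", 1:4),
                                        c("A", "B", "C"))))
}

# write a .shared file from a header line + body lines
writeSharedLines <- function(lines) {
  f <- tempfile(fileext = ".shared")
  writeLines(lines, f)
  f
}

sharedFixture <- function() {
  # 2 samples x 3 OTUs, counts [[5,0],[1,2],[0,3]] (taxa x samples)
  writeSharedLines(c(
    "label\tGroup\tnumOtus\tOtu001\tOtu002\tOtu003",
    "0.97\tsampleA\t3\t5\t1\t0",
    "0.97\tsampleB\t3\t0\t2\t3"))
}
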