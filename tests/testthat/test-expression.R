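writeToyFiles <- function(dir, mat, annot, samples) {
  ef <- file.path(dir, "expr.tsv")
  af <- file.path(dir, "annot.tsv")
  sf <- file.path(dir, "samples.tsv")
  write.table(data.frame(probe_id = rownames(mat), mat, check.names = FALSE),
              ef, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(annot, af, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(samples, sf, sep = "\t", quote = FALSE, row.names = FALSE)
  c(ef, af, sf)
}

test_that("loadExpression joins annotation, orders columns and round-trips", {
  samples <- toySampleSheet()
  mat <- toyMatrix(list(G1 = c(5, 5, 5, 8), G2 = c(4, 4, 4, 4),
                        G3 = c(6, 6, 6, 6), G4 = c(7, 7, 7, 7)))
  annot <- toyAnnotation(mat, rep(c("human", "mouse"), each = 2),
                         c("G1", "G2", "G3", "G4"))
  dir <- withr::local_tempdir()
  f <- writeToyFiles(dir, mat[, rev(samples$sample_id)], annot, samples)
  se <- loadExpression(f[1], f[2], f[3])
  expect_equal(dim(se), c(4L, 12L))
  expect_identical(colnames(se), samples$sample_id)  # sheet order wins
  expect_identical(unname(assay(se)["G1_p1", ]), unname(mat["G1_p1", ]))

  ## write-then-load reproduces values bit-identically
  dir2 <- withr::local_tempdir()
  writeExpression(se, file.path(dir2, "e.tsv"), file.path(dir2, "a.tsv"),
                  file.path(dir2, "s.tsv"))
  se2 <- loadExpression(file.path(dir2, "e.tsv"), file.path(dir2, "a.tsv"),
                        file.path(dir2, "s.tsv"))
  expect_identical(assay(se2), assay(se))
})

test_that("loadExpression drops unannotated probes and fails loudly otherwise", {
  samples <- toySampleSheet()
  mat <- toyMatrix(list(G1 = c(5, 5, 5, 8), G2 = c(4, 4, 4, 4),
                        G3 = c(6, 6, 6, 6)))
  annot <- toyAnnotation(mat, "human", c("G1", "G2", "G3"))
  dir <- withr::local_tempdir()
  f <- writeToyFiles(dir, mat, annot[-2, ], samples)
  expect_message(se <- loadExpression(f[1], f[2], f[3]), "1 unannotated")
  expect_equal(nrow(se), 2L)

  ## non-numeric cell is fatal with its position
  bad <- mat
  storage.mode(bad) <- "character"
  bad["G2_p1", "brafi_2"] <- "oops"
  f <- writeToyFiles(dir, bad, annot, samples)
  expect_error(loadExpression(f[1], f[2], f[3]), "G2_p1.*brafi_2")

  ## sample missing from the sheet is fatal and named
  f <- writeToyFiles(dir, mat, annot, samples[-12, ])
  expect_error(loadExpression(f[1], f[2], f[3]), "combo_3")
})

test_that("multi-gene probes are duplicated into per-gene rows", {
  samples <- toySampleSheet()
  mat <- toyMatrix(list(G1 = c(5, 5, 5, 8)))
  annot <- data.frame(probe_id = "G1_p1", species = "human",
                      gene = "GA;GB", cross_hyb = 0L)
  dir <- withr::local_tempdir()
  f <- writeToyFiles(dir, mat, annot, samples)
  expect_message(se <- loadExpression(f[1], f[2], f[3]), "multi-gene")
  expect_equal(nrow(se), 2L)
  expect_setequal(rowData(se)$gene, c("GA", "GB"))
  expect_identical(unname(assay(se)[1, ]), unname(assay(se)[2, ]))
})

test_that("significance prefilter keeps p < alpha strictly, in any condition", {
  p <- rbind(a = c(0.20, 0.04, 0.50),
             b = c(0.20, 0.60, 0.90),
             c = c(0.05, 0.05, 0.05))
  keep <- significancePrefilter(p, 0.05)
  expect_identical(keep, c(a = TRUE, b = FALSE, c = FALSE))
  expect_error(significancePrefilter(rbind(c(1.2, 0.1, 0.1))), "\\[0, 1\\]")
})

test_that("cross-hybridizing removal is a pure row deletion and idempotent", {
  se <- randomProbeSE(10, 5, seed = 3)
  expect_identical(assay(removeCrossHybridizing(se, character())), assay(se))
  bl <- rownames(se)[c(2, 5, 9)]
  out <- removeCrossHybridizing(se, bl)
  expect_identical(rownames(out), setdiff(rownames(se), bl))  # set-difference oracle
  expect_identical(assay(out), assay(se)[setdiff(rownames(se), bl), ])
  expect_identical(assay(removeCrossHybridizing(out, bl)), assay(out))
  expect_message(removeCrossHybridizing(se, c(bl, "NOPE")), "1 blacklist")
  empty <- removeCrossHybridizing(se, rownames(se))
  expect_equal(nrow(empty), 0L)
})

test_that("collapse keeps the largest-mean probe with lexicographic ties", {
  samples <- toySampleSheet()
  mat <- rbind(pB = rep(7.2, 12), pA = rep(5.0, 12),
               pC = rep(4, 12), pD = rep(4, 12))
  colnames(mat) <- samples$sample_id
  annot <- data.frame(probe_id = rownames(mat), species = "human",
                      gene = c("G", "G", "H", "H"), cross_hyb = 0L)
  se <- makeXenoExperiment(mat, annot, samples)
  out <- collapseToGenes(se)
  expect_identical(rowData(out)$probe_id,
                   c("pB",   # largest mean wins
                     "pC"))  # tie broken by smallest probe id
  expect_identical(exprLevel(out), "gene")
  expect_identical(unname(assay(out)["human:G", ]), rep(7.2, 12))
})

test_that("collapse agrees with a brute-force per-gene scan on random fixtures", {
  for (seed in 1:10) {
    se <- randomProbeSE(50, 12, seed = seed)
    out <- collapseToGenes(se)
    rd <- rowData(se)
    key <- paste(rd$species, rd$gene)
    expect_equal(nrow(out), length(unique(key)))
    mu <- rowMeans(assay(se))
    for (k in unique(key)) {   # exhaustive scan oracle
      i <- which(key == k)
      best <- i[order(-mu[i], rd$probe_id[i])][1]
      expect_identical(
        unname(assay(out)[paste(rd$species[best], rd$gene[best], sep = ":"), ]),
        unname(assay(se)[best, ]))
    }
    ## pure selection: gene-level values are a sub-multiset of probe values
    expect_true(all(assay(out) %in% assay(se)))
  }
})

test_that("expression calls respect floor and scope", {
  samples <- toySampleSheet()
  mat <- toyMatrix(list(G1 = c(4.0, 4.1, 4.0, 9.0), G2 = c(3, 3, 3, 3)))
  annot <- toyAnnotation(mat, "human", c("G1", "G2"))
  gse <- collapseToGenes(makeXenoExperiment(mat, annot, samples))
  call <- expressionCall(gse, floor = 6.0)
  expect_identical(expressedGenes(call, "human"), "G1")
  expect_false(any(call$expressed[call$gene == "G2"]))
  ## floor -Inf: every gene expressed
  expect_true(all(expressionCall(gse, floor = -Inf)$expressed))
  ## scope restricted to arms where G1 is low
  call2 <- expressionCall(gse, floor = 6.0, scope = c("control", "brafi"))
  expect_length(expressedGenes(call2, "human"), 0L)
  expect_error(expressionCall(gse, scope = character()), "scope")
})

test_that("auto floor is the per-species median of gene mean intensities", {
  samples <- toySampleSheet()
  mat <- toyMatrix(list(H1 = rep(2, 4), H2 = rep(5, 4), H3 = rep(9, 4),
                        M1 = rep(4, 4), M2 = rep(6, 4), M3 = rep(8, 4)))
  genes <- sub("_p1$", "", rownames(mat))
  sp <- ifelse(substr(genes, 1, 1) == "H", "human", "mouse")
  gse <- collapseToGenes(makeXenoExperiment(mat, toyAnnotation(mat, sp, genes),
                                            samples))
  call <- expressionCall(gse)
  expect_equal(unique(call$floor[call$species == "human"]), 5)
  expect_equal(unique(call$floor[call$species == "mouse"]), 6)
  expect_setequal(expressedGenes(call, "human"), c("H2", "H3"))  # >= floor
})
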