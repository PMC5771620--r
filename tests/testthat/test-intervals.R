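test_that("intersect_peaks keeps list_b coordinates, deduplicated and sorted", {
  a <- iv("chr1:100-200")
  b <- iv("chr1:150-250")
  expect_equal(intersect_peaks(a, b), iv("chr1:150-250"))
  # same span on another chromosome never overlaps
  expect_equal(nrow(intersect_peaks(a, iv("chr2:100-200"))), 0L)
  # two a-peaks hitting one b-peak yield the b-peak once
  a2 <- iv("chr1:100-160", "chr1:180-220")
  expect_equal(intersect_peaks(a2, b), iv("chr1:150-250"))
  # output sorted by (chrom, start) and a subset of list_b
  b2 <- iv("chr2:5-30", "chr1:150-250", "chr1:90-120")
  out <- intersect_peaks(iv("chr1:100-200", "chr2:10-20"), b2)
  expect_equal(out, iv("chr1:90-120", "chr1:150-250", "chr2:5-30"))
  expect_true(nrow(out) <= nrow(b2))
})

test_that("malformed intervals are rejected with their record index", {
  bad <- tibble::tibble(chrom = "chr1", start = c(10L, 50L), end = c(20L, 40L))
  expect_error(intersect_peaks(bad, iv("chr1:1-5")), "row\\(s\\): 2")
  expect_error(intersect_peaks(iv("chr1:1-5"), bad), "row\\(s\\): 2")
})

test_that("intersect and overlap partition agree with the all-pairs oracle", {
  set.seed(42)
  for (rep in 1:3) {
    a <- rand_intervals(300)
    b <- rand_intervals(300)
    hit <- bf_overlaps_any(b, a)
    out <- intersect_peaks(a, b)
    expected <- dplyr::arrange(dplyr::distinct(b[hit, ]), chrom, start)
    expect_equal(out, expected)

    part <- overlap_with_sites(b, a)
    expect_equal(part$in_site, bf_overlaps_any(b, a))
    expect_equal(sum(part$in_site) + sum(!part$in_site), nrow(b))
  }
})

test_that("peaks are assigned to genes with the documented location categories", {
  genes <- toy_genes()
  peak_at <- function(center) {
    tibble::tibble(chrom = "chr1", start = center - 50L, end = center + 51L)
  }
  res <- assign_peaks(peak_at(95000L), genes)
  expect_equal(res$gene_id, "G")
  expect_equal(as.character(res$location), "EXTENDED_PROMOTER")
  expect_equal(res$distance_to_tss, -5000)

  res <- assign_peaks(peak_at(100500L), genes)
  expect_equal(as.character(res$location), "TSS")

  res <- assign_peaks(peak_at(121500L), genes)
  expect_true(is.na(res$gene_id))
  expect_equal(as.character(res$location), "INTERGENIC")

  res <- assign_peaks(peak_at(110000L), genes)
  expect_equal(as.character(res$location), "GENE_BODY")

  # minus-strand gene H: TSS at 320000, upstream means larger coordinates
  res <- assign_peaks(peak_at(325000L), genes)
  expect_equal(res$gene_id, "H")
  expect_equal(as.character(res$location), "EXTENDED_PROMOTER")
  expect_equal(res$distance_to_tss, -5000)
  res <- assign_peaks(peak_at(299500L), genes)
  expect_equal(res$gene_id, "H")
  expect_equal(as.character(res$location), "GENE_BODY")
})

test_that("nearest TSS wins multi-gene hits, ties by gene id", {
  genes <- tibble::tibble(
    chrom = "chr1", start = c(10000L, 30000L), end = c(25000L, 45000L),
    strand = "+", gene_id = c("B", "A")
  )
  # center 28000: in B's body window and A's upstream window;
  # |28000-30000| < |28000-10000| so A wins
  pk <- tibble::tibble(chrom = "chr1", start = 27950L, end = 28051L)
  expect_equal(assign_peaks(pk, genes)$gene_id, "A")
  # equidistant TSSs -> lexicographically smallest id
  genes2 <- tibble::tibble(
    chrom = "chr1", start = c(20000L, 40000L), end = c(35000L, 55000L),
    strand = "+", gene_id = c("Z", "A")
  )
  pk2 <- tibble::tibble(chrom = "chr1", start = 29950L, end = 30051L)
  expect_equal(assign_peaks(pk2, genes2)$gene_id, "A")
})

test_that("every peak gets exactly one location and categories partition", {
  set.seed(7)
  genes <- toy_genes()
  centers <- sample(80000:340000, 200)
  peaks <- tibble::tibble(chrom = "chr1", start = centers - 50L,
                          end = centers + 51L)
  res <- assign_peaks(peaks, genes)
  expect_false(anyNA(res$location))
  expect_equal(sum(is.na(res$gene_id)),
               sum(res$location == "INTERGENIC"))
  expect_equal(sum(res$location != "INTERGENIC") +
                 sum(res$location == "INTERGENIC"), nrow(peaks))
})

test_that("location categories are invariant under coordinate mirroring", {
  set.seed(11)
  L <- 500000L
  genes <- toy_genes()
  centers <- sample(80000:340000, 150)
  peaks <- tibble::tibble(chrom = "chr1", start = centers - 50L,
                          end = centers + 51L)  # odd width: exact mirror
  mirror_iv <- function(x) {
    dplyr::arrange(
      dplyr::mutate(x, s = L - end, e = L - start, start = s, end = e,
                    s = NULL, e = NULL),
      start
    )
  }
  genes_m <- genes |>
    dplyr::mutate(s = L - end, e = L - start, start = s, end = e,
                  strand = ifelse(strand == "+", "-", "+"), s = NULL, e = NULL)
  res <- assign_peaks(peaks, genes)
  res_m <- assign_peaks(mirror_iv(peaks), genes_m)
  tab <- table(res$location)
  tab_m <- table(res_m$location)
  expect_equal(as.vector(tab), as.vector(tab_m))
  # per-peak: order reverses under mirroring within equal-width peaks
  key <- order(res$peak_center)
  key_m <- order(-res_m$peak_center)
  expect_equal(as.character(res$location[key]),
               as.character(res_m$location[key_m]))
})

test_that("unknown gene strand is rejected", {
  g <- tibble::tibble(chrom = "chr1", start = 1L, end = 100L, strand = ".",
                      gene_id = "X")
  expect_error(assign_peaks(iv("chr1:10-20"), g), "strand")
})

test_that("top_sites_by_signal keeps the n best scores, ties by position", {
  s <- tibble::tibble(chrom = "chr1", start = 0:4 * 100L,
                      end = 0:4 * 100L + 50L, score = c(1, 5, 3, 2, 4))
  expect_equal(sort(top_sites_by_signal(s, 3)$score), c(3, 4, 5))
  expect_equal(top_sites_by_signal(s, 99), dplyr::arrange(s, dplyr::desc(score)))
  expect_error(top_sites_by_signal(dplyr::select(s, -score), 3), "score")

  set.seed(13)
  big <- rand_intervals(1000)
  big$score <- sample(1:50, 1000, replace = TRUE)  # heavy ties
  got <- top_sites_by_signal(big, 400)
  full <- big[order(-big$score, big$chrom, big$start), ]
  expect_equal(got, tibble::as_tibble(full[1:400, ]))
})

test_that("BED and gene tables round-trip through files", {
  p <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(10L, 5L),
                      end = c(60L, 25L), name = c("p1", "p2"),
                      score = c(7, 2), strand = c("+", "-"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(p, f)
  expect_equal(read_bed(f), p)

  g <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(toy_genes(), g)
  back <- read_genes(g)
  expect_equal(back$tss, c(100000L, 320000L))
  expect_equal(back$tts, c(120000L, 300000L))

  # BED6 layout with gene id in the name column
  b6 <- withr::local_tempfile(fileext = ".bed")
  write_bed(dplyr::mutate(toy_genes(), name = gene_id, score = 0,
                          .after = "end"), b6)
  back2 <- read_genes(b6)
  expect_equal(back2$gene_id, c("G", "H"))
  expect_equal(back2$tss, back$tss)
})
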