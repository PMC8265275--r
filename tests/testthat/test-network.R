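de_stub <- function(ids, dirs, lfc = NULL) {
  tibble::tibble(feature_id = ids, direction = dirs,
                 log2fc = lfc %||% ifelse(dirs == "Up", 1.5, -1.5),
                 q = 0, significant = dirs %in% c("Up", "Down"))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

site_stub <- function(mirna, target, passes = TRUE) {
  tibble::tibble(mirna_id = mirna, target_id = target,
                 target_start = 10L, target_end = 30L, seed_class = "7mer-WC",
                 align_score = 215, align_mfe = -50, hybrid_mfe = -50,
                 passes = passes)
}

test_that("build_del_deg_networks partitions pairs by shared direction", {
  cis <- tibble::tibble(lnc_id = c("lncA", "lncB", "lncC"),
                        mrna_id = c("g1", "g2", "g3"),
                        mrna_is_de = TRUE)
  de_lnc <- de_stub(c("lncA", "lncB", "lncC"), c("Up", "Down", "Up"))
  de_gene <- de_stub(c("g1", "g2", "g3"), c("Up", "Down", "Down"))
  nets <- build_del_deg_networks(cis, de_lnc, de_gene)
  expect_equal(nrow(nets$up$edges), 1L)
  expect_equal(nets$up$edges$source, "lncA")
  expect_equal(nrow(nets$down$edges), 1L)
  expect_equal(nets$down$edges$source, "lncB")
  # discordant pair in neither network
  expect_false("lncC" %in% c(nets$up$edges$source, nets$down$edges$source))

  empty <- build_del_deg_networks(cis[0, ], de_lnc, de_gene)
  expect_equal(nrow(empty$up$edges), 0L)
  expect_equal(nrow(empty$down$edges), 0L)
})

test_that("build_des_deg_network dedups sites into signed edges", {
  sites <- dplyr::bind_rows(site_stub("m1", "g1"), site_stub("m1", "g1"),
                            site_stub("m2", "g2"), site_stub("m3", "g3", passes = FALSE))
  de_mirna <- de_stub(c("m1", "m2", "m3"), c("Down", "Up", "Down"))
  de_gene <- de_stub(c("g1", "g2", "g3"), c("Up", "Up", "Up"))
  net <- build_des_deg_network(sites, de_mirna, de_gene)
  expect_equal(nrow(net$edges), 2L) # duplicate collapsed, non-passing dropped
  expect_equal(net$edges$sign[net$edges$source == "m1"], "negative")
  expect_equal(net$edges$sign[net$edges$source == "m2"], "positive")

  expect_equal(nrow(build_des_deg_network(sites[0, ], de_mirna, de_gene)$edges), 0L)
})

test_that("shared_genes intersects edge targets symmetrically", {
  nodes <- tibble::tibble(
    id = c("l1", "m1", "FNIP2", "PEX5L", "GBE1", "LPIN1"),
    kind = c("lncRNA", "miRNA", "gene", "gene", "gene", "gene")
  )
  netA <- cx_network(tibble::tibble(source = "l1", interaction = "cis",
                                    target = c("FNIP2", "PEX5L", "GBE1")), nodes)
  netB <- cx_network(tibble::tibble(source = "m1", interaction = "mirna-target",
                                    target = c("FNIP2", "PEX5L", "LPIN1")), nodes)
  expect_equal(shared_genes(netA, netB), c("FNIP2", "PEX5L"))
  expect_equal(shared_genes(netA, netB), shared_genes(netB, netA))
  netC <- cx_network(tibble::tibble(source = "m1", interaction = "mirna-target",
                                    target = "LPIN1"), nodes)
  expect_equal(shared_genes(netA, netC), character(0))
  expect_equal(shared_genes(netA, netA), sort(c("FNIP2", "PEX5L", "GBE1")))
})

test_that("nominate_axes requires all three evidence edges and flags consistency", {
  cis <- tibble::tibble(lnc_id = "lncF", mrna_id = "FNIP2", mrna_is_de = TRUE)
  gene_sites <- site_stub("m24", "FNIP2")
  sponge <- site_stub("m24", "lncF")
  de_lnc <- de_stub("lncF", "Up", 1.20)
  de_mirna <- de_stub("m24", "Down", -1.14101)
  de_gene <- de_stub("FNIP2", "Up", 1.01)

  axes <- nominate_axes("FNIP2", cis, gene_sites, sponge, de_lnc, de_mirna, de_gene)
  expect_equal(nrow(axes), 1L)
  expect_true(axes$consistent)
  expect_equal(axes$lnc_id, "lncF")
  expect_equal(axes$rank_score, 1.20 + 1.14101 + 1.01)

  # without the sponge site the gene is merely shared
  none <- nominate_axes("FNIP2", cis, gene_sites, sponge[0, ],
                        de_lnc, de_mirna, de_gene)
  expect_equal(nrow(none), 0L)

  expect_equal(nrow(nominate_axes(character(0), cis, gene_sites, sponge,
                                  de_lnc, de_mirna, de_gene)), 0L)

  # co-directional miRNA breaks the ceRNA pattern but is still reported
  axes2 <- nominate_axes("FNIP2", cis, gene_sites, sponge,
                         de_lnc, de_stub("m24", "Up", 1.0), de_gene)
  expect_false(axes2$consistent)
})

test_that("axis evidence is referentially intact in the exported networks", {
  cis <- tibble::tibble(lnc_id = "lncF", mrna_id = "FNIP2", mrna_is_de = TRUE)
  gene_sites <- site_stub("m24", "FNIP2")
  sponge <- site_stub("m24", "lncF")
  de_lnc <- de_stub("lncF", "Up")
  de_mirna <- de_stub("m24", "Down")
  de_gene <- de_stub("FNIP2", "Up")
  axes <- nominate_axes("FNIP2", cis, gene_sites, sponge, de_lnc, de_mirna, de_gene)
  nets <- build_del_deg_networks(cis, de_lnc, de_gene)
  mnet <- build_des_deg_network(gene_sites, de_mirna, de_gene)
  for (i in seq_len(nrow(axes))) {
    expect_true(any(nets$up$edges$source == axes$lnc_id[i] &
                      nets$up$edges$target == axes$gene_id[i]))
    expect_true(any(mnet$edges$source == axes$mirna_id[i] &
                      mnet$edges$target == axes$gene_id[i]))
  }
})
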