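netFixture <- function() {
    co <- rbind(d1 = c(TF1 = 0.5, TF2 = 0),
                d2 = c(TF1 = 0.3, TF2 = 0.4),
                d3 = c(TF1 = -0.2, TF2 = 0.6))
    links <- data.frame(dhs_id = c("d1", "d2", "d2", "d3"),
                        gene_id = c("gA", "gA", "gB", "gB"),
                        r = c(0.8, 0.9, 0.75, 0.95),
                        distance = c(1e4, 2e4, -3e4, 5e3),
                        stringsAsFactors = FALSE)
    list(co = co, links = links)
}

test_that("edge weights are products, aggregated and standardized", {
    fx <- netFixture()
    ## single TF, single path: raw weight beta * r, std 0 by convention
    n1 <- buildNetwork("TF2", fx$co,
                       fx$links[fx$links$dhs_id == "d3", ])
    expect_equal(n1@edges$raw_weight, 0.6 * 0.95)
    expect_equal(n1@edges$std_weight, 0)

    ## two edges standardize to +/- 1/sqrt(2) (sample SD), mean 0, sd 1
    n2 <- buildNetwork("TF1", fx$co,
                       fx$links[fx$links$dhs_id %in% c("d1", "d2") &
                                fx$links$gene_id == "gA" |
                                fx$links$dhs_id == "d2" &
                                fx$links$gene_id == "gB", ])
    ## TF1 -> gA via d1 (0.5*0.8) + d2 (0.3*0.9); TF1 -> gB via d2
    raw <- sort(n2@edges$raw_weight)
    expect_equal(raw, sort(c(0.5 * 0.8 + 0.3 * 0.9, 0.3 * 0.75)))
    expect_equal(mean(n2@edges$std_weight), 0, tolerance = 1e-12)
    expect_equal(sd(n2@edges$std_weight), 1, tolerance = 1e-12)
    expect_equal(sort(n2@edges$std_weight),
                 c(-1, 1) / sqrt(2), tolerance = 1e-12)

    ## negative-coefficient DHSs are not TF targets
    full <- buildNetwork(c("TF1", "TF2"), fx$co, fx$links)
    expect_false(any(full@edges$tf == "TF1" &
                     grepl("d3", full@edges$via_dhs)))
    ## TF with no positive DHS stays an isolated node
    co0 <- fx$co; co0[, "TF2"] <- -1
    iso <- buildNetwork("TF2", co0, fx$links)
    expect_equal(nrow(iso@edges), 0L)
    expect_true("TF2" %in% iso@nodes$node)
    expect_error(buildNetwork("TFX", fx$co, fx$links), "TFX")
})

test_that("removing a stage TF removes exactly its incident edges", {
    fx <- netFixture()
    full <- buildNetwork(c("TF1", "TF2"), fx$co, fx$links)
    one <- buildNetwork("TF1", fx$co, fx$links)
    expect_equal(one@edges[, c("tf", "gene", "raw_weight")],
                 full@edges[full@edges$tf == "TF1",
                            c("tf", "gene", "raw_weight")],
                 ignore_attr = TRUE)
    ## restandardization restores mean 0 / sd 1 after the change
    re <- restandardizeEdges(one)
    if (nrow(re@edges) > 1) {
        expect_lt(abs(mean(re@edges$std_weight)), 1e-10)
        expect_lt(abs(sd(re@edges$std_weight) - 1), 1e-10)
    }
})

test_that("centralities match closed forms on stars and paths", {
    co <- matrix(1, 4, 1, dimnames = list(paste0("d", 1:4), "TFhub"))
    links <- data.frame(dhs_id = paste0("d", 1:4),
                        gene_id = paste0("g", 1:4),
                        r = 0.9, distance = 0, stringsAsFactors = FALSE)
    star <- buildNetwork("TFhub", co, links)
    cent <- nodeCentrality(star)
    expect_equal(cent$centrality[cent$node == "TFhub"], 1)
    expect_equal(cent$centrality[cent$node == "g1"], 0.25)

    ## 3-node path: middle node has normalized betweenness 1
    co2 <- rbind(dx = c(TFm = 1), dy = c(TFm = 1))
    links2 <- data.frame(dhs_id = c("dx", "dy"),
                         gene_id = c("gLeft", "gRight"), r = 0.8,
                         distance = 0, stringsAsFactors = FALSE)
    path <- buildNetwork("TFm", co2, links2)
    bw <- nodeCentrality(path, "betweenness")
    expect_equal(bw$centrality[bw$node == "TFm"], 1)
    expect_equal(bw$centrality[bw$node == "gLeft"], 0)

    ev <- nodeCentrality(star, "eigenvector")
    expect_equal(max(ev$centrality), 1)

    empty <- buildNetwork(character(), co, links)
    expect_equal(nrow(nodeCentrality(empty)), 0L)
})

test_that("top-target filtering keeps n strongest with lexicographic ties", {
    genes <- sprintf("g%02d", 1:60)
    co <- matrix(1, 60, 1, dimnames = list(sprintf("d%02d", 1:60), "TF1"))
    links <- data.frame(dhs_id = rownames(co), gene_id = genes,
                        r = c(seq(0.99, 0.75, length.out = 58), 0.8, 0.8),
                        distance = 0, stringsAsFactors = FALSE)
    net <- buildNetwork("TF1", co, links)
    top <- topTargets(net, n = 50)
    expect_equal(nrow(top@edges), 50L)
    small <- topTargets(net, n = 100)
    expect_equal(nrow(small@edges), 60L)          # "up to" semantics

    ## exact tie in |std_weight|: smaller gene id wins
    co3 <- matrix(1, 3, 1, dimnames = list(paste0("d", 1:3), "TF1"))
    l3 <- data.frame(dhs_id = paste0("d", 1:3),
                     gene_id = c("gC", "gA", "gB"),
                     r = c(0.9, 0.8, 0.8), distance = 0,
                     stringsAsFactors = FALSE)
    n3 <- buildNetwork("TF1", co3, l3)
    t2 <- topTargets(n3, n = 2)
    expect_setequal(t2@edges$gene, c("gC", "gA"))
})

test_that("networks serialize as GraphML and edge lists, even when empty", {
    fx <- netFixture()
    net <- buildNetwork(c("TF1", "TF2"), fx$co, fx$links)
    g <- withr::local_tempfile(fileext = ".graphml")
    e <- withr::local_tempfile(fileext = ".tsv")
    writeNetwork(net, g, e)
    back <- igraph::read_graph(g, format = "graphml")
    expect_equal(igraph::gsize(back), nrow(net@edges))
    expect_equal(nrow(readTable(e)), nrow(net@edges))

    co0 <- fx$co * 0
    empty <- buildNetwork("TF1", co0, fx$links)
    g0 <- withr::local_tempfile(fileext = ".graphml")
    e0 <- withr::local_tempfile(fileext = ".tsv")
    writeNetwork(empty, g0, e0)
    expect_true(file.exists(g0))
    expect_equal(nrow(readTable(e0)), 0L)
})
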