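# The ECG-RCLSTM-Net: a 1-D ResNet consuming the whole zero-padded signal
# (global features) and a CNN-LSTM consuming the variable-length sequence of
# two-second beat segments (local features); the two branch outputs are
# concatenated into a fully connected classification layer. Auxiliary heads
# on each branch support the staged pretraining recipe.

make_res1d_block <- function(ctx, name, c_in, c_out) {
  conv1 <- nn_conv1d(ctx, paste0(name, ".conv1"), c_in, c_out, 7L, stride = 2L)
  bn1 <- nn_bn(ctx, paste0(name, ".bn1"), c_out)
  conv2 <- nn_conv1d(ctx, paste0(name, ".conv2"), c_out, c_out, 7L, stride = 1L)
  bn2 <- nn_bn(ctx, paste0(name, ".bn2"), c_out)
  skip <- nn_conv1d(ctx, paste0(name, ".skip"), c_in, c_out, 1L, stride = 2L,
                    pad = 0L)
  function(x, L, n, train) {
    c1 <- conv1(x, L, n)
    a <- ad_relu(bn1(c1$y, train))
    c2 <- conv2(a, c1$L, n)
    b <- bn2(c2$y, train)
    s <- skip(x, L, n)
    list(y = ad_relu(ad_add(b, s$y)), L = c2$L)
  }
}

build_rclstm <- function(config) {
  ctx <- nn_ctx()
  rc <- config$res_ch
  bc <- config$beat_ch
  hB <- config$lstm_hidden
  fb <- 2L * bc # per-beat feature dimension after the beat CNN
  n_classes <- config$n_classes

  # global branch: 1-D ResNet over the padded signal
  stem <- nn_conv1d(ctx, "resnet.stem", 1L, rc[1L], 15L, stride = 2L)
  bn0 <- nn_bn(ctx, "resnet.bn0", rc[1L])
  rblocks <- lapply(1:3, function(i)
    make_res1d_block(ctx, sprintf("resnet.b%d", i), rc[i], rc[i + 1L]))

  # local branch: shared beat CNN + LSTM over the beat sequence
  bconv1 <- nn_conv1d(ctx, "clstm.cnn1", 1L, bc, 7L, stride = 2L)
  bbn1 <- nn_bn(ctx, "clstm.cnnbn1", bc)
  bconv2 <- nn_conv1d(ctx, "clstm.cnn2", bc, fb, 7L, stride = 2L)
  bbn2 <- nn_bn(ctx, "clstm.cnnbn2", fb)
  bconv3 <- nn_conv1d(ctx, "clstm.cnn3", fb, fb, 7L, stride = 2L)
  bbn3 <- nn_bn(ctx, "clstm.cnnbn3", fb)
  lstm <- nn_lstm(ctx, "clstm.lstm", fb, hB)
  empty_emb <- nn_par(ctx, "clstm.empty", matrix(0, 1L, hB))

  fuse_head <- nn_dense(ctx, "fuse.head", rc[4L] + hB, n_classes)
  resnet_head <- nn_dense(ctx, "resnet_head.fc", rc[4L], n_classes)
  clstm_head <- nn_dense(ctx, "clstm_head.fc", hB, n_classes)
  cnn_head <- nn_dense(ctx, "cnn_head.fc", fb, n_classes)

  encode_resnet <- function(batch, train) {
    s <- stem(batch$sig, batch$L, batch$n)
    x <- ad_relu(bn0(s$y, train))
    L <- s$L
    for (blk in rblocks) {
      out <- blk(x, L, batch$n, train)
      x <- out$y; L <- out$L
    }
    ad_t(ad_pool_cols(x, L)) # N x C
  }
  beat_features <- function(batch, train) {
    # all beats of the batch through the shared CNN: B x fb (or NULL)
    B <- sum(batch$beat_counts)
    if (B == 0L) return(NULL)
    c1 <- bconv1(batch$beats, batch$beat_len, B)
    x <- ad_relu(bbn1(c1$y, train))
    c2 <- bconv2(x, c1$L, B)
    x <- ad_relu(bbn2(c2$y, train))
    c3 <- bconv3(x, c2$L, B)
    x <- ad_relu(bbn3(c3$y, train))
    ad_t(ad_pool_cols(x, c3$L)) # B x fb
  }
  encode_clstm <- function(batch, train) {
    feats <- beat_features(batch, train)
    offsets <- cumsum(c(0L, batch$beat_counts))
    hs <- vector("list", batch$n)
    for (r in seq_len(batch$n)) {
      k <- batch$beat_counts[r]
      if (k == 0L) {
        hs[[r]] <- empty_emb
      } else {
        xs <- lapply(seq_len(k), function(j)
          ad_slice_rows(feats, offsets[r] + j))
        hs[[r]] <- lstm(xs, 1L)
      }
    }
    ad_rbind(hs) # N x hB
  }
  forward <- function(batch, train) {
    fuse_head(ad_cbind(list(encode_resnet(batch, train),
                            encode_clstm(batch, train))))
  }
  forward_resnet <- function(batch, train) resnet_head(encode_resnet(batch, train))
  forward_clstm <- function(batch, train) clstm_head(encode_clstm(batch, train))
  forward_cnn <- function(batch, train) {
    # CNN-pretraining path: mean beat feature per record -> linear head
    feats <- beat_features(batch, train)
    offsets <- cumsum(c(0L, batch$beat_counts))
    rows <- vector("list", batch$n)
    for (r in seq_len(batch$n)) {
      k <- batch$beat_counts[r]
      rows[[r]] <- if (k == 0L) {
        ad_const(matrix(0, 1L, fb))
      } else {
        ad_matmul(ad_const(matrix(1 / k, 1L, k)),
                  ad_slice_rows(feats, offsets[r] + seq_len(k)))
      }
    }
    cnn_head(ad_rbind(rows))
  }
  structure(list(family = "rclstm", size = config$size,
                 n_classes = n_classes, config = config, ctx = ctx,
                 forward = forward, forward_resnet = forward_resnet,
                 forward_clstm = forward_clstm, forward_cnn = forward_cnn),
            class = c("afib_rclstm", "afib_nn", "afib_model"))
}
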