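#!/usr/bin/env python
"""Reference runtime for eegdecoder portable model files.

Loads an `eegdecoder-portable-v1` JSON model (base64 float64 tensors) and
runs the evaluation-mode forward pass in NumPy, independently of the R
implementation.

Usage:
    python portable_runtime.py MODEL.json INPUT.bin N OUTPUT.bin

INPUT.bin holds N x C x T float64 samples in C order (little endian);
OUTPUT.bin receives N x n_classes float64 scores in C order.

Tensor layout conventions (documented in the exporter):
  * conv weights: (out_channels, in_channels * kernel), column index
    k * in_channels + c (kernel-position major); R column-major storage
    means the flat base64 stream is Fortran order.
  * linear weights: (d_in, d_out), applied as  y = x @ W + b.
"""
import base64
import json
import sys

import numpy as np


def decode(t):
    dims = t["dims"] if isinstance(t["dims"], list) else [t["dims"]]
    v = np.frombuffer(base64.b64decode(t["data"]), dtype="<f8")
    return v.reshape(dims, order="F") if len(dims) > 1 else v


def conv1d_valid(x, w, b, cin, kernel):
    """x: (cin, T); w: (cout, cin*kernel) with column index k*cin + c."""
    t_out = x.shape[1] - kernel + 1
    win = np.lib.stride_tricks.sliding_window_view(x, t_out, axis=1)
    # win: (cin, kernel, t_out); flatten to (kernel*cin, t_out) k-major
    col = win.transpose(1, 0, 2).reshape(kernel * cin, t_out)
    return w @ col + b[:, None]


def bn_eval(x, gamma, beta, mean, var, eps=1e-5):
    inv = 1.0 / np.sqrt(var + eps)
    return (x - mean[:, None]) * (gamma * inv)[:, None] + beta[:, None]


def elu(x):
    return np.where(x < 0, np.expm1(x), x)


def maxpool(x, p):
    t = x.shape[1] // p
    return x[:, : t * p].reshape(x.shape[0], t, p).max(axis=2)


def avgpool(x, p):
    t = x.shape[1] // p
    return x[:, : t * p].reshape(x.shape[0], t, p).mean(axis=2)


def softmax(s):
    e = np.exp(s - s.max(axis=-1, keepdims=True))
    return e / e.sum(axis=-1, keepdims=True)


def layernorm(z, gamma, beta, eps=1e-5):
    mu = z.mean(axis=1, keepdims=True)
    v = ((z - mu) ** 2).mean(axis=1, keepdims=True)
    return (z - mu) / np.sqrt(v + eps) * gamma + beta


def decoder_forward(cfg, P, S, x):
    c1 = conv1d_valid(x, P["conv1.w"], P["conv1.b"],
                      cfg["in_channels"], cfg["conv1_kernel"])
    c1 = elu(bn_eval(c1, P["bn1.gamma"], P["bn1.beta"],
                     S["bn1.mean"], S["bn1.var"]))
    c1 = maxpool(c1, cfg["pool"])
    c2 = conv1d_valid(c1, P["conv2.w"], P["conv2.b"],
                      cfg["conv1_out"], cfg["conv2_kernel"])
    c2 = elu(bn_eval(c2, P["bn2.gamma"], P["bn2.beta"],
                     S["bn2.mean"], S["bn2.var"]))
    c2 = maxpool(c2, cfg["pool"])

    z = c2.T  # (T', d_model)
    h = cfg["attention_heads"]
    dk = cfg["d_model"] // h
    for layer in range(1, cfg["encoder_layers"] + 1):
        pre = "enc%d." % layer
        q = z @ P[pre + "wq"] + P[pre + "bq"]
        k = z @ P[pre + "wk"] + P[pre + "bk"]
        v = z @ P[pre + "wv"] + P[pre + "bv"]
        o = np.empty_like(z)
        for hi in range(h):
            cs = slice(hi * dk, (hi + 1) * dk)
            a = softmax(q[:, cs] @ k[:, cs].T / np.sqrt(dk))
            o[:, cs] = a @ v[:, cs]
        mh = o @ P[pre + "wo"] + P[pre + "bo"]
        z1 = layernorm(z + mh, P[pre + "ln1.gamma"], P[pre + "ln1.beta"])
        f = np.maximum(z1 @ P[pre + "ffn.w1"] + P[pre + "ffn.b1"], 0)
        f2 = f @ P[pre + "ffn.w2"] + P[pre + "ffn.b2"]
        z = layernorm(z1 + f2, P[pre + "ln2.gamma"], P[pre + "ln2.beta"])

    pooled = z.mean(axis=0)
    return pooled @ P["head.w"] + P["head.b"]


def eegnet_forward(cfg, P, S, x):
    C, T = x.shape
    f1, d, f2 = cfg["F1"], cfg["D"], cfg["F2"]
    kt = cfg["temporal_kernel"]
    pl, pr = (kt - 1) // 2, kt - 1 - (kt - 1) // 2
    xp = np.pad(x, ((0, 0), (pl, pr)))
    # temporal filter bank per channel -> (f1, C, T)
    r = np.stack([conv1d_valid(xp[c:c + 1], P["conv1.w"], np.zeros(f1), 1, kt)
                  for c in range(C)], axis=1)
    rm = r.reshape(f1, -1)
    r = bn_eval(rm, P["bn1.gamma"], P["bn1.beta"],
                S["bn1.mean"], S["bn1.var"]).reshape(f1, C, T)
    # depthwise spatial: (f2, C) grouped per temporal filter
    z = np.empty((f2, T))
    for f in range(f1):
        rows = slice(f * d, (f + 1) * d)
        z[rows] = P["dw.w"][rows] @ r[f]
    z = elu(bn_eval(z, P["bn2.gamma"], P["bn2.beta"],
                    S["bn2.mean"], S["bn2.var"]))
    z = avgpool(z, cfg["pool1"])
    ks = cfg["separable_kernel"]
    sl, sr = (ks - 1) // 2, ks - 1 - (ks - 1) // 2
    zp = np.pad(z, ((0, 0), (sl, sr)))
    dwt = np.stack([np.convolve(zp[m], P["sep.dw"][m][::-1], mode="valid")
                    for m in range(f2)])
    pw = P["sep.pw"] @ dwt
    pw = elu(bn_eval(pw, P["bn3.gamma"], P["bn3.beta"],
                     S["bn3.mean"], S["bn3.var"]))
    pw = avgpool(pw, cfg["pool2"])
    flat = pw.reshape(-1, order="F")  # map fastest, matching the R flatten
    return flat @ P["head.w"] + P["head.b"]


def main():
    model_path, input_path, n, out_path = (
        sys.argv[1], sys.argv[2], int(sys.argv[3]), sys.argv[4])
    with open(model_path) as fh:
        obj = json.load(fh)
    if obj.get("format") != "eegdecoder-portable-v1":
        sys.exit("unsupported model format")
    cfg = obj["config"]
    P = {k: decode(v) for k, v in obj["params"].items()}
    S = {k: decode(v) for k, v in obj["state"].items()}
    C, T = cfg["in_channels"], cfg["input_samples"]
    x = np.fromfile(input_path, dtype="<f8").reshape(n, C, T)
    fwd = decoder_forward if obj["architecture"] == "eegdecoder" \
        else eegnet_forward
    out = np.stack([fwd(cfg, P, S, x[i]) for i in range(n)])
    out.astype("<f8").tofile(out_path)


if __name__ == "__main__":
    main()
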