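#!/usr/bin/env python
"""Bridge between .h5ad containers and the scembedeval plain-text dataset
directory format (obs.tsv / embedding.tsv / counts.tsv / manifest.json).

Usage:
    h5ad_bridge.py export <in.h5ad> <out_dir> [emb_key]
    h5ad_bridge.py import <in_dir> <out.h5ad> [emb_key]
"""
import json
import os
import sys

import numpy as np
import pandas as pd


def _dense(x):
    if x is None:
        return None
    if hasattr(x, "toarray"):
        x = x.toarray()
    return np.asarray(x, dtype=float)


def export(path, out_dir, emb_key):
    import anndata as ad

    adata = ad.read_h5ad(path)
    if adata.obs_names.duplicated().any():
        raise SystemExit("format error: duplicated cell identifiers")
    os.makedirs(out_dir, exist_ok=True)

    obs = pd.DataFrame({"cell_id": adata.obs_names.astype(str)})
    if "cell_type" not in adata.obs.columns:
        raise SystemExit("format error: obs lacks a cell_type column")
    obs["cell_type"] = adata.obs["cell_type"].astype(str).values
    for key in ("batch", "condition"):
        if key in adata.obs.columns:
            obs[key] = adata.obs[key].astype(str).values
    if "spatial" in adata.obsm:
        sp = np.asarray(adata.obsm["spatial"], dtype=float)
        obs["spatial_x"] = [repr(float(v)) for v in sp[:, 0]]
        obs["spatial_y"] = [repr(float(v)) for v in sp[:, 1]]
    obs.to_csv(os.path.join(out_dir, "obs.tsv"), sep="\t", index=False)

    manifest = {
        "format": "scembedeval-dataset",
        "version": 1,
        "n_cells": adata.n_obs,
        "has_embedding": emb_key in adata.obsm,
        "has_counts": False,
    }

    def write_matrix(M, cols, fname):
        df = pd.DataFrame(M, columns=cols)
        df.insert(0, "cell_id", adata.obs_names.astype(str).values)
        with open(os.path.join(out_dir, fname), "w") as fh:
            fh.write("\t".join(df.columns) + "\n")
            for _, row in df.iterrows():
                vals = [row.iloc[0]] + [repr(float(v)) for v in row.iloc[1:]]
                fh.write("\t".join(vals) + "\n")

    if manifest["has_embedding"]:
        E = _dense(adata.obsm[emb_key])
        write_matrix(E, ["d%d" % (j + 1) for j in range(E.shape[1])],
                     "embedding.tsv")

    counts = None
    if "counts" in adata.layers:
        counts = _dense(adata.layers["counts"])
    elif adata.X is not None:
        counts = _dense(adata.X)
    if counts is not None and counts.shape[1] > 0:
        manifest["has_counts"] = True
        manifest["counts_assay"] = (
            "counts" if np.all(counts >= 0) and
            np.allclose(counts, np.round(counts)) else "logexpr")
        write_matrix(counts, list(adata.var_names.astype(str)), "counts.tsv")

    with open(os.path.join(out_dir, "manifest.json"), "w") as fh:
        json.dump(manifest, fh)


def import_(in_dir, out_path, emb_key):
    import anndata as ad

    with open(os.path.join(in_dir, "manifest.json")) as fh:
        manifest = json.load(fh)
    obs = pd.read_csv(os.path.join(in_dir, "obs.tsv"), sep="\t", dtype=str)
    obs = obs.set_index("cell_id")
    obs.index.name = None

    X = None
    var_names = None
    layers = {}
    obsm = {}
    if manifest.get("has_counts"):
        cdf = pd.read_csv(os.path.join(in_dir, "counts.tsv"), sep="\t",
                          index_col=0)
        X = cdf.to_numpy(dtype=float)
        var_names = list(cdf.columns)
    if manifest.get("has_embedding"):
        edf = pd.read_csv(os.path.join(in_dir, "embedding.tsv"), sep="\t",
                          index_col=0)
        obsm[emb_key] = edf.to_numpy(dtype=float)
    if {"spatial_x", "spatial_y"} <= set(obs.columns):
        obsm["spatial"] = obs[["spatial_x", "spatial_y"]].to_numpy(dtype=float)
        obs = obs.drop(columns=["spatial_x", "spatial_y"])

    if X is None:
        X = np.zeros((len(obs), 0))
    adata = ad.AnnData(X=X, obs=obs, obsm=obsm)
    if var_names is not None:
        adata.var_names = var_names
        if manifest.get("counts_assay", "counts") == "counts":
            adata.layers["counts"] = X.copy()
    adata.write_h5ad(out_path)


def main(argv):
    if len(argv) < 3:
        raise SystemExit(__doc__)
    verb, src, dst = argv[0], argv[1], argv[2]
    emb_key = argv[3] if len(argv) > 3 else "X_emb"
    if verb == "export":
        export(src, dst, emb_key)
    elif verb == "import":
        import_(src, dst, emb_key)
    else:
        raise SystemExit("unknown verb: %s" % verb)


if __name__ == "__main__":
    main(sys.argv[1:])
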