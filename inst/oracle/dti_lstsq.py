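#!/usr/bin/env python
"""Independent log-linear DTI fitter used as a test oracle.

Reads JSON from the path in argv[1]:
  {"cases": [{"bvals": [...], "bvecs": [[x,y,z],...], "s0": S0,
              "signals": [...]}, ...]}
and writes JSON to argv[2]: {"tensors": [[Dxx,Dxy,Dxz,Dyy,Dyz,Dzz],...]}.

The design matrix is built here from first principles (b * outer(g,g))
and solved with numpy.linalg.lstsq, with no code shared with the R
implementation under test.
"""
import json
import sys

import numpy as np


def fit_case(case):
    bvals = np.asarray(case["bvals"], dtype=float)
    bvecs = np.asarray(case["bvecs"], dtype=float)
    y = np.log(float(case["s0"]) / np.asarray(case["signals"], dtype=float))
    rows = []
    for b, g in zip(bvals, bvecs):
        B = b * np.outer(g, g)
        rows.append([B[0, 0], 2 * B[0, 1], 2 * B[0, 2],
                     B[1, 1], 2 * B[1, 2], B[2, 2]])
    X = np.asarray(rows)
    coef, *_ = np.linalg.lstsq(X, y, rcond=None)
    return coef.tolist()


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    tensors = [fit_case(c) for c in payload["cases"]]
    with open(sys.argv[2], "w") as fh:
        json.dump({"tensors": tensors}, fh)


if __name__ == "__main__":
    main()
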