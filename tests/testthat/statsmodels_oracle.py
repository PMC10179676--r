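"""Independent GEE reference: fits every dataset in a stacked CSV with
statsmodels (binomial logit, exchangeable working correlation, robust
covariance) and writes per-dataset coefficients and robust SEs as JSON.

Usage: python statsmodels_oracle.py <input.csv> <output.json>
CSV columns: dataset, cluster, y, then covariate columns.
"""
import json
import sys

import pandas as pd
import statsmodels.api as sm
from statsmodels.genmod.cov_struct import Exchangeable
from statsmodels.genmod.families import Binomial
from statsmodels.genmod.generalized_estimating_equations import GEE

inp, outp = sys.argv[1], sys.argv[2]
d = pd.read_csv(inp)
covs = [c for c in d.columns if c not in ("dataset", "cluster", "y")]
res = {}
for ds, sub in d.groupby("dataset"):
    X = sm.add_constant(sub[covs])
    fit = GEE(sub["y"], X, groups=sub["cluster"], family=Binomial(),
              cov_struct=Exchangeable()).fit(maxiter=300, ctol=1e-10)
    res[str(ds)] = {"coef": list(fit.params), "se": list(fit.bse)}
with open(outp, "w") as fh:
    json.dump(res, fh)
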