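#!/usr/bin/env python
"""Independent reference computation of the 107 radiomics features and the
ICC(2,1) cross-check values, written as frozen CSV fixtures for the R test
suite.

Implemented from the standard feature definitions with numpy/scipy/skimage
(connected components via scipy.ndimage.label, mesh surface via
skimage.measure.marching_cubes), sharing only the documented conventions of
the R package (fixed-bin-width discretization anchored at the ROI minimum,
13 unique 3D directions at distance 1, GLDM dependence size j = neighbour
count + 1, voxel-center 2D diameters, population-covariance axis lengths).
"""

import numpy as np
import pandas as pd
from scipy import ndimage
from skimage import measure
import pingouin as pg

SPACING = np.array([1.2, 1.5, 3.0])
BIN_WIDTH = 0.005
SHIFT = 1.0

roi = pd.read_csv("tests/testthat/fixtures/oracle_roi.csv")
dims = (14, 13, 8)
vol = np.zeros(dims)
mask = np.zeros(dims, dtype=bool)
for _, r in roi.iterrows():
    vol[int(r.x) - 1, int(r.y) - 1, int(r.z) - 1] = r.value
    mask[int(r.x) - 1, int(r.y) - 1, int(r.z) - 1] = True

vals = vol[mask]
N = vals.size

# ---- discretization -------------------------------------------------------
lev = np.floor((vals - vals.min()) / BIN_WIDTH + 1e-9).astype(int) + 1
Ng = lev.max()
gray = np.zeros(dims, dtype=int)
gray[mask] = lev

feats = {}

# ---- first order ----------------------------------------------------------
xs = vals + SHIFT
m = vals.mean()
m2 = ((vals - m) ** 2).mean()
m3 = ((vals - m) ** 3).mean()
m4 = ((vals - m) ** 4).mean()
p = np.bincount(np.floor((vals - vals.min()) / BIN_WIDTH + 1e-9).astype(int))
p = p[p > 0] / N
p10, p25, p75, p90 = np.percentile(vals, [10, 25, 75, 90])
robust = vals[(vals >= p10) & (vals <= p90)]
vv = SPACING.prod()
feats.update({
    ("firstorder", "Energy"): np.sum(xs ** 2),
    ("firstorder", "TotalEnergy"): vv * np.sum(xs ** 2),
    ("firstorder", "Entropy"): -np.sum(p * np.log2(p)),
    ("firstorder", "Minimum"): vals.min(),
    ("firstorder", "10Percentile"): p10,
    ("firstorder", "90Percentile"): p90,
    ("firstorder", "Maximum"): vals.max(),
    ("firstorder", "Mean"): m,
    ("firstorder", "Median"): np.median(vals),
    ("firstorder", "InterquartileRange"): p75 - p25,
    ("firstorder", "Range"): vals.max() - vals.min(),
    ("firstorder", "MeanAbsoluteDeviation"): np.abs(vals - m).mean(),
    ("firstorder", "RobustMeanAbsoluteDeviation"):
        np.abs(robust - robust.mean()).mean(),
    ("firstorder", "RootMeanSquared"): np.sqrt(np.mean(xs ** 2)),
    ("firstorder", "Skewness"): m3 / m2 ** 1.5,
    ("firstorder", "Kurtosis"): m4 / m2 ** 2,
    ("firstorder", "Variance"): m2,
    ("firstorder", "Uniformity"): np.sum(p ** 2),
})

# ---- shape ----------------------------------------------------------------
pad = np.pad(mask.astype(float), 1)
verts, faces, _, _ = measure.marching_cubes(pad, level=0.5, spacing=SPACING)
sa = measure.mesh_surface_area(verts, faces)
tet = verts[faces]
mesh_vol = abs(np.einsum("ij,ij->i", tet[:, 0],
                         np.cross(tet[:, 1], tet[:, 2])).sum()) / 6.0
co = np.argwhere(mask) + 1
co_mm = co * SPACING

def max_pair(pts):
    if len(pts) < 2:
        return 0.0
    d = np.sqrt(((pts[:, None, :] - pts[None, :, :]) ** 2).sum(-1))
    return d.max()

max3d = max_pair(verts)

def diam2d(plane_axis, keep):
    best = 0.0
    for v in np.unique(co[:, plane_axis]):
        pts = co_mm[co[:, plane_axis] == v][:, keep]
        best = max(best, max_pair(pts))
    return best

cov = np.cov(co_mm.T, bias=True)
ev = np.sort(np.linalg.eigvalsh(cov))[::-1]
ev = np.clip(ev, 0, None)
feats.update({
    ("shape", "MeshVolume"): mesh_vol,
    ("shape", "VoxelVolume"): N * vv,
    ("shape", "SurfaceArea"): sa,
    ("shape", "SurfaceVolumeRatio"): sa / mesh_vol,
    ("shape", "Sphericity"): (36 * np.pi * mesh_vol ** 2) ** (1 / 3) / sa,
    ("shape", "Maximum3DDiameter"): max3d,
    ("shape", "Maximum2DDiameterSlice"): diam2d(2, [0, 1]),
    ("shape", "Maximum2DDiameterColumn"): diam2d(0, [1, 2]),
    ("shape", "Maximum2DDiameterRow"): diam2d(1, [0, 2]),
    ("shape", "MajorAxisLength"): 4 * np.sqrt(ev[0]),
    ("shape", "MinorAxisLength"): 4 * np.sqrt(ev[1]),
    ("shape", "LeastAxisLength"): 4 * np.sqrt(ev[2]),
    ("shape", "Elongation"): np.sqrt(ev[1] / ev[0]),
    ("shape", "Flatness"): np.sqrt(ev[2] / ev[0]),
})

# ---- directions -----------------------------------------------------------
DIRS = []
for dz in (-1, 0, 1):
    for dy in (-1, 0, 1):
        for dx in (-1, 0, 1):
            if (dz > 0 or (dz == 0 and dy > 0)
                    or (dz == 0 and dy == 0 and dx > 0)):
                DIRS.append((dx, dy, dz))
assert len(DIRS) == 13

def shifted(a, d, fill=0):
    out = np.full_like(a, fill)
    sx = slice(max(d[0], 0), a.shape[0] + min(d[0], 0))
    sy = slice(max(d[1], 0), a.shape[1] + min(d[1], 0))
    sz = slice(max(d[2], 0), a.shape[2] + min(d[2], 0))
    tx = slice(max(-d[0], 0), a.shape[0] + min(-d[0], 0))
    ty = slice(max(-d[1], 0), a.shape[1] + min(-d[1], 0))
    tz = slice(max(-d[2], 0), a.shape[2] + min(-d[2], 0))
    out[sx, sy, sz] = a[tx, ty, tz]
    return out

# ---- GLCM -----------------------------------------------------------------
def glcm_features():
    per_dir = []
    for d in DIRS:
        sm = shifted(mask, d)
        sg = shifted(gray, d)
        valid = mask & sm
        if not valid.any():
            continue
        i, j = gray[valid], sg[valid]
        P = np.zeros((Ng, Ng))
        np.add.at(P, (i - 1, j - 1), 1)
        P = P + P.T
        p = P / P.sum()
        per_dir.append(glcm_one(p))
    return {k: np.mean([d[k] for d in per_dir]) for k in per_dir[0]}

def glcm_one(p):
    lv = np.arange(1, Ng + 1)
    I = lv[:, None] * np.ones((1, Ng))
    J = I.T
    px = p.sum(1)
    mu = (I * p).sum()
    sig2 = ((I - mu) ** 2 * p).sum()
    delta = np.abs(I - J)
    pd_ = np.array([p[delta == k].sum() for k in range(Ng)])
    ps_ = np.array([p[(I + J) == k].sum() for k in range(2, 2 * Ng + 1)])
    kd = np.arange(Ng)
    ks = np.arange(2, 2 * Ng + 1)
    da = (kd * pd_).sum()
    pos = p > 0
    hxy = -(p[pos] * np.log2(p[pos])).sum()
    pxpy = np.outer(px, px)
    ok = pos & (pxpy > 0)
    hxy1 = -(p[ok] * np.log2(pxpy[ok])).sum()
    okm = pxpy > 0
    hxy2 = -(pxpy[okm] * np.log2(pxpy[okm])).sum()
    hx = -(px[px > 0] * np.log2(px[px > 0])).sum()
    present = px > 0
    pp = p[np.ix_(present, present)]
    pxp = px[present]
    if present.sum() < 2:
        mcc = 1.0
    else:
        A = pp / np.sqrt(pxp)[None, :]
        M = A @ A.T / np.sqrt(np.outer(pxp, pxp))
        evs = np.sort(np.linalg.eigvalsh((M + M.T) / 2))[::-1]
        mcc = np.sqrt(max(evs[1], 0))
    corr = ((I * J * p).sum() - mu ** 2) / sig2 if sig2 > 1e-12 else 1.0
    return {
        "Autocorrelation": (I * J * p).sum(),
        "ClusterProminence": ((I + J - 2 * mu) ** 4 * p).sum(),
        "ClusterShade": ((I + J - 2 * mu) ** 3 * p).sum(),
        "ClusterTendency": ((I + J - 2 * mu) ** 2 * p).sum(),
        "Contrast": ((I - J) ** 2 * p).sum(),
        "Correlation": corr,
        "DifferenceAverage": da,
        "DifferenceEntropy": -(pd_[pd_ > 0] * np.log2(pd_[pd_ > 0])).sum(),
        "DifferenceVariance": ((kd - da) ** 2 * pd_).sum(),
        "Id": (p / (1 + delta)).sum(),
        "Idm": (p / (1 + delta ** 2)).sum(),
        "Idmn": (p / (1 + delta ** 2 / Ng ** 2)).sum(),
        "Idn": (p / (1 + delta / Ng)).sum(),
        "Imc1": (hxy - hxy1) / hx if hx > 0 else 0.0,
        "Imc2": np.sqrt(max(1 - np.exp(-2 * (hxy2 - hxy)), 0)),
        "InverseVariance": (p[delta > 0] / delta[delta > 0] ** 2).sum(),
        "JointAverage": mu,
        "JointEnergy": (p ** 2).sum(),
        "JointEntropy": hxy,
        "MaximumProbability": p.max(),
        "MCC": mcc,
        "SumAverage": (ks * ps_).sum(),
        "SumEntropy": -(ps_[ps_ > 0] * np.log2(ps_[ps_ > 0])).sum(),
        "SumSquares": sig2,
    }

for k, v in glcm_features().items():
    feats[("glcm", k)] = v

# ---- GLRLM ----------------------------------------------------------------
def glrlm_features():
    per_dir = []
    for d in DIRS:
        runs = []
        start = mask & ~shifted(mask & (gray == shifted(gray, d)),
                                tuple(-c for c in d))
        # walk runs explicitly
        seen = np.zeros(dims, dtype=bool)
        for pos0 in np.argwhere(mask):
            pos0 = tuple(pos0)
            prev = (pos0[0] - d[0], pos0[1] - d[1], pos0[2] - d[2])
            inside_prev = all(0 <= prev[a] < dims[a] for a in range(3))
            if inside_prev and mask[prev] and gray[prev] == gray[pos0]:
                continue  # not a run start
            # walk forward
            length = 1
            cur = pos0
            while True:
                nxt = (cur[0] + d[0], cur[1] + d[1], cur[2] + d[2])
                if not all(0 <= nxt[a] < dims[a] for a in range(3)):
                    break
                if not mask[nxt] or gray[nxt] != gray[pos0]:
                    break
                length += 1
                cur = nxt
            runs.append((gray[pos0], length))
        runs = np.array(runs)
        per_dir.append(glrlm_one(runs))
    return {k: np.mean([d[k] for d in per_dir]) for k in per_dir[0]}

def glrlm_one(runs):
    i = runs[:, 0].astype(float)
    r = runs[:, 1].astype(float)
    Nr = len(runs)
    gl = np.bincount(runs[:, 0])[1:].astype(float)
    rl = np.bincount(runs[:, 1])[1:].astype(float)
    pij = {}
    for a, b in runs:
        pij[(a, b)] = pij.get((a, b), 0) + 1
    pv = np.array(list(pij.values())) / Nr
    return {
        "GrayLevelNonUniformity": (gl ** 2).sum() / Nr,
        "GrayLevelNonUniformityNormalized": (gl ** 2).sum() / Nr ** 2,
        "GrayLevelVariance": ((i - i.mean()) ** 2).mean(),
        "HighGrayLevelRunEmphasis": (i ** 2).mean(),
        "LongRunEmphasis": (r ** 2).mean(),
        "LongRunHighGrayLevelEmphasis": (i ** 2 * r ** 2).mean(),
        "LongRunLowGrayLevelEmphasis": (r ** 2 / i ** 2).mean(),
        "LowGrayLevelRunEmphasis": (1 / i ** 2).mean(),
        "RunEntropy": -(pv * np.log2(pv)).sum(),
        "RunLengthNonUniformity": (rl ** 2).sum() / Nr,
        "RunLengthNonUniformityNormalized": (rl ** 2).sum() / Nr ** 2,
        "RunPercentage": Nr / N,
        "RunVariance": ((r - r.mean()) ** 2).mean(),
        "ShortRunEmphasis": (1 / r ** 2).mean(),
        "ShortRunHighGrayLevelEmphasis": (i ** 2 / r ** 2).mean(),
        "ShortRunLowGrayLevelEmphasis": (1 / (i ** 2 * r ** 2)).mean(),
    }

for k, v in glrlm_features().items():
    feats[("glrlm", k)] = v

# ---- GLSZM ----------------------------------------------------------------
zones = []
struct = np.ones((3, 3, 3), dtype=int)
for lvl in np.unique(lev):
    lab, nlab = ndimage.label(gray == lvl, structure=struct)
    for z in range(1, nlab + 1):
        zones.append((lvl, int((lab == z).sum())))
zones = np.array(zones)
zi = zones[:, 0].astype(float)
zs = zones[:, 1].astype(float)
Nz = len(zones)
glz = np.bincount(zones[:, 0])[1:].astype(float)
szz = np.bincount(zones[:, 1])[1:].astype(float)
pzs = {}
for a, b in zones:
    pzs[(a, b)] = pzs.get((a, b), 0) + 1
pzv = np.array(list(pzs.values())) / Nz
feats.update({
    ("glszm", "GrayLevelNonUniformity"): (glz ** 2).sum() / Nz,
    ("glszm", "GrayLevelNonUniformityNormalized"): (glz ** 2).sum() / Nz ** 2,
    ("glszm", "GrayLevelVariance"): ((zi - zi.mean()) ** 2).mean(),
    ("glszm", "HighGrayLevelZoneEmphasis"): (zi ** 2).mean(),
    ("glszm", "LargeAreaEmphasis"): (zs ** 2).mean(),
    ("glszm", "LargeAreaHighGrayLevelEmphasis"): (zi ** 2 * zs ** 2).mean(),
    ("glszm", "LargeAreaLowGrayLevelEmphasis"): (zs ** 2 / zi ** 2).mean(),
    ("glszm", "LowGrayLevelZoneEmphasis"): (1 / zi ** 2).mean(),
    ("glszm", "SizeZoneNonUniformity"): (szz ** 2).sum() / Nz,
    ("glszm", "SizeZoneNonUniformityNormalized"): (szz ** 2).sum() / Nz ** 2,
    ("glszm", "SmallAreaEmphasis"): (1 / zs ** 2).mean(),
    ("glszm", "SmallAreaHighGrayLevelEmphasis"): (zi ** 2 / zs ** 2).mean(),
    ("glszm", "SmallAreaLowGrayLevelEmphasis"): (1 / (zi ** 2 * zs ** 2)).mean(),
    ("glszm", "ZoneEntropy"): -(pzv * np.log2(pzv)).sum(),
    ("glszm", "ZonePercentage"): Nz / N,
    ("glszm", "ZoneVariance"): ((zs - zs.mean()) ** 2).mean(),
})

# ---- NGTDM ----------------------------------------------------------------
offs = [(dx, dy, dz) for dx in (-1, 0, 1) for dy in (-1, 0, 1)
        for dz in (-1, 0, 1) if (dx, dy, dz) != (0, 0, 0)]
nb_sum = np.zeros(dims)
nb_cnt = np.zeros(dims)
for d in offs:
    nb_sum += shifted(gray * mask, d)
    nb_cnt += shifted(mask.astype(float), d)
has_nb = mask & (nb_cnt > 0)
iv_all = gray[has_nb]
av = nb_sum[has_nb] / nb_cnt[has_nb]
nvp = int(has_nb.sum())
s_i = np.zeros(Ng + 1)
n_i = np.zeros(Ng + 1)
for l in range(1, Ng + 1):
    sel = iv_all == l
    n_i[l] = sel.sum()
    s_i[l] = np.abs(l - av[sel]).sum()
p_i = n_i / nvp
pres = np.where(p_i > 0)[0]
pp_, ss_, ii_ = p_i[pres], s_i[pres], pres.astype(float)
ngp = len(pres)
ps_sum = (pp_ * ss_).sum()
feats.update({
    ("ngtdm", "Busyness"):
        ps_sum / np.abs(np.subtract.outer(ii_ * pp_, ii_ * pp_)).sum()
        if ngp > 1 else 0.0,
    ("ngtdm", "Coarseness"): 1 / ps_sum if ps_sum > 0 else 1e6,
    ("ngtdm", "Complexity"):
        (np.abs(np.subtract.outer(ii_, ii_))
         * np.add.outer(pp_ * ss_, pp_ * ss_)
         / np.add.outer(pp_, pp_)).sum() / nvp if ngp > 1 else 0.0,
    ("ngtdm", "Contrast"):
        (np.outer(pp_, pp_) * np.subtract.outer(ii_, ii_) ** 2).sum()
        / (ngp * (ngp - 1)) * ss_.sum() / nvp if ngp > 1 else 0.0,
    ("ngtdm", "Strength"):
        (np.add.outer(pp_, pp_) * np.subtract.outer(ii_, ii_) ** 2).sum()
        / ss_.sum() if ss_.sum() > 0 else 0.0,
})

# ---- GLDM -----------------------------------------------------------------
dep = np.zeros(dims, dtype=int)
for d in offs:
    sm = shifted(mask, d)
    sg = shifted(gray, d)
    dep += (mask & sm & (np.abs(gray - sg) <= 0)).astype(int)
di_ = gray[mask].astype(float)
dj_ = dep[mask].astype(float) + 1
Nzd = N
glD = np.bincount(gray[mask])[1:].astype(float)
dpD = np.bincount(dep[mask] + 1)[1:].astype(float)
pijd = {}
for a, b in zip(gray[mask], dep[mask] + 1):
    pijd[(a, b)] = pijd.get((a, b), 0) + 1
pdv = np.array(list(pijd.values())) / Nzd
feats.update({
    ("gldm", "DependenceEntropy"): -(pdv * np.log2(pdv)).sum(),
    ("gldm", "DependenceNonUniformity"): (dpD ** 2).sum() / Nzd,
    ("gldm", "DependenceNonUniformityNormalized"): (dpD ** 2).sum() / Nzd ** 2,
    ("gldm", "DependenceVariance"): ((dj_ - dj_.mean()) ** 2).mean(),
    ("gldm", "GrayLevelNonUniformity"): (glD ** 2).sum() / Nzd,
    ("gldm", "GrayLevelVariance"): ((di_ - di_.mean()) ** 2).mean(),
    ("gldm", "HighGrayLevelEmphasis"): (di_ ** 2).mean(),
    ("gldm", "LargeDependenceEmphasis"): (dj_ ** 2).mean(),
    ("gldm", "LargeDependenceHighGrayLevelEmphasis"): (di_ ** 2 * dj_ ** 2).mean(),
    ("gldm", "LargeDependenceLowGrayLevelEmphasis"): (dj_ ** 2 / di_ ** 2).mean(),
    ("gldm", "LowGrayLevelEmphasis"): (1 / di_ ** 2).mean(),
    ("gldm", "SmallDependenceEmphasis"): (1 / dj_ ** 2).mean(),
    ("gldm", "SmallDependenceHighGrayLevelEmphasis"): (di_ ** 2 / dj_ ** 2).mean(),
    ("gldm", "SmallDependenceLowGrayLevelEmphasis"): (1 / (di_ ** 2 * dj_ ** 2)).mean(),
})

out = pd.DataFrame(
    [(fam, name, val) for (fam, name), val in feats.items()],
    columns=["family", "feature", "value"],
)
out["value"] = out["value"].astype(float)
out.to_csv("tests/testthat/fixtures/radiomics_oracle.csv", index=False)
print("features:", len(out), "Ng:", Ng, "N:", N)

# ---- ICC cross-check via pingouin -----------------------------------------
tabs = pd.read_csv("tests/testthat/fixtures/icc_tables.csv")
rows = []
for t, g in tabs.groupby("table"):
    long = g.melt(id_vars=["table", "row"], value_vars=["r1", "r2"],
                  var_name="rater", value_name="value")
    icc = pg.intraclass_corr(long, targets="row", raters="rater",
                             ratings="value")
    r = icc[icc.Type.isin(["ICC2", "ICC(A,1)"])].iloc[0]
    rows.append({"table": t, "icc": r.ICC, "f": r.F, "pval": r.pval,
                 "ci_lo": r.CI95[0], "ci_hi": r.CI95[1]})
pd.DataFrame(rows).to_csv("tests/testthat/fixtures/icc_expected.csv",
                          index=False)
print("icc expected written")
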