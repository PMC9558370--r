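"""Chemistry backend: RDKit / scikit-learn operations behind the R surface.

Invoked as:  python chem_backend.py <request.json> <response.json>

The request is {"op": <name>, ...op-specific fields...}; the response is
{"ok": true, ...} or {"ok": false, "error": <message>}.  All molecule
exchange uses SMILES with attachment points encoded as dummy atoms
carrying atom-map numbers: map 1 = core-facing site, maps 2..k =
termini-facing sites.
"""

import itertools
import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, BRICS, Descriptors, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def _mol(smiles, what="molecule"):
    m = Chem.MolFromSmiles(smiles)
    if m is None:
        raise ValueError(f"unparseable SMILES for {what}: {smiles!r}")
    return m


def _strip_dummies(mol):
    """Remove dummy atoms (for substructure matching of a marked core)."""
    rw = Chem.RWMol(mol)
    idx = [a.GetIdx() for a in rw.GetAtoms() if a.GetAtomicNum() == 0]
    for i in sorted(idx, reverse=True):
        rw.RemoveAtom(i)
    m = rw.GetMol()
    Chem.SanitizeMol(m)
    return m


def op_canonicalize(req):
    out, bad = [], []
    for s in req["smiles"]:
        m = Chem.MolFromSmiles(s)
        if m is None:
            out.append(None)
            bad.append(s)
        else:
            out.append(Chem.MolToSmiles(m))
    return {"canonical": out, "invalid": bad}


# ---------------------------------------------------------------- decompose

def _fragment_sites(frag):
    """(atom index, map label) pairs for mapped dummy atoms of a fragment."""
    return [(a.GetIdx(), a.GetAtomMapNum()) for a in frag.GetAtoms()
            if a.GetAtomicNum() == 0 and a.GetAtomMapNum() > 0]


def _dummies_to_h(mol, keep_maps):
    """Replace dummy atoms whose map is not in keep_maps by hydrogens."""
    rw = Chem.RWMol(mol)
    for a in rw.GetAtoms():
        if a.GetAtomicNum() == 0 and a.GetAtomMapNum() not in keep_maps:
            a.SetAtomicNum(1)
            a.SetIsotope(0)
            a.SetAtomMapNum(0)
    m = rw.GetMol()
    Chem.SanitizeMol(m)
    return Chem.RemoveHs(m)


def _decompose_one(mol, core):
    """Split one ligand into linker/terminus fragments around `core`.

    Returns a list of dicts (smiles, kind, n_sites).  Linkers keep map 1
    (core-facing) plus maps 2..k for each BRICS cut toward a terminus;
    termini keep a single attachment dummy with map 2.
    """
    side = Chem.ReplaceCore(mol, core, labelByIndex=False)
    if side is None:
        return None
    # mark the core-facing dummies (ReplaceCore labels them by isotope)
    for a in side.GetAtoms():
        if a.GetAtomicNum() == 0:
            a.SetIsotope(0)
            a.SetAtomMapNum(1)
    frags = []
    for comp in Chem.GetMolFrags(side, asMols=True, sanitizeFrags=True):
        if not any(a.GetAtomMapNum() == 1 for a in comp.GetAtoms()):
            continue  # ReplaceCore returns nothing else, but be safe
        broken = BRICS.BreakBRICSBonds(comp)
        for piece in Chem.GetMolFrags(broken, asMols=True, sanitizeFrags=True):
            is_linker = any(a.GetAtomMapNum() == 1 and a.GetAtomicNum() == 0
                            for a in piece.GetAtoms())
            if is_linker:
                nxt = 2
                for a in piece.GetAtoms():
                    if a.GetAtomicNum() == 0 and a.GetAtomMapNum() != 1:
                        a.SetIsotope(0)
                        a.SetAtomMapNum(nxt)
                        nxt += 1
                piece = Chem.RemoveHs(piece)
                frags.append({"smiles": Chem.MolToSmiles(piece),
                              "kind": "linker",
                              "n_termini_sites": nxt - 2})
            else:
                first = True
                for a in piece.GetAtoms():
                    if a.GetAtomicNum() == 0:
                        if first:
                            a.SetIsotope(0)
                            a.SetAtomMapNum(2)
                            first = False
                        else:
                            a.SetAtomMapNum(0)
                piece = _dummies_to_h(piece, keep_maps={2})
                frags.append({"smiles": Chem.MolToSmiles(piece),
                              "kind": "terminus",
                              "n_termini_sites": 0})
    return frags


def op_decompose(req):
    core = _strip_dummies(_mol(req["core"], "core"))
    fragments, skipped = [], []
    seen = {}
    for lig in req["ligands"]:
        mol = _mol(lig["smiles"], f"ligand {lig['ligand_id']}")
        if not mol.HasSubstructMatch(core):
            skipped.append(lig["ligand_id"])
            continue
        frs = _decompose_one(mol, core)
        if frs is None:
            skipped.append(lig["ligand_id"])
            continue
        for fr in frs:
            key = (fr["smiles"], fr["kind"])
            if key not in seen:
                fr["origin_ligand_id"] = lig["ligand_id"]
                seen[key] = fr
                fragments.append(fr)
    return {"fragments": fragments, "skipped": skipped}


# ---------------------------------------------------------------- enumerate

def _zip_parts(parts):
    combo = parts[0]
    for p in parts[1:]:
        combo = Chem.CombineMols(combo, p)
    try:
        prod = Chem.molzip(combo)
        Chem.SanitizeMol(prod)
        return prod
    except Exception:
        return None


def _assemble(core, linker, site_assignment):
    """core + linker (+ termini bound to linker sites) -> (smiles, rgroup)."""
    parts = [core, Chem.Mol(linker)]
    for site, term in site_assignment:
        t = Chem.Mol(term)
        for a in t.GetAtoms():
            if a.GetAtomicNum() == 0 and a.GetAtomMapNum() == 2:
                a.SetAtomMapNum(site)
        parts.append(t)
    prod = _zip_parts(parts)
    if prod is None:
        return None
    used = {s for s, _ in site_assignment}
    try:
        prod = _dummies_to_h(prod, keep_maps=set())
    except Exception:
        return None
    # R-group record: same assembly without the core, core-facing site -> H
    rparts = parts[1:]
    rg = _zip_parts(rparts) if len(rparts) > 1 else Chem.Mol(rparts[0])
    if rg is None:
        rgs = None
    else:
        try:
            rgs = Chem.MolToSmiles(_dummies_to_h(rg, keep_maps=set()))
        except Exception:
            rgs = None
    return {"smiles": Chem.MolToSmiles(prod), "rgroup_smiles": rgs}


def op_enumerate(req):
    core = _mol(req["core"], "core")
    if not any(a.GetAtomicNum() == 0 and a.GetAtomMapNum() == 1
               for a in core.GetAtoms()):
        raise ValueError("core must carry an attachment dummy [*:1]")
    linkers = [(_mol(s, "linker"), s) for s in req["linkers"]]
    termini = [_mol(s, "terminus") for s in req["termini"]]
    max_t = int(req["max_termini"])
    products, seen = [], set()
    n_invalid = 0
    for li, (linker, lsmi) in enumerate(linkers):
        sites = sorted(m for _, m in _fragment_sites(linker) if m >= 2)
        kmax = min(max_t, len(sites)) if termini else 0
        for k in range(kmax + 1):
            for subset in itertools.combinations(sites, k):
                for assign in itertools.product(range(len(termini)), repeat=k):
                    pairing = [(s, termini[t]) for s, t in zip(subset, assign)]
                    res = _assemble(core, linker, pairing)
                    if res is None:
                        n_invalid += 1
                        continue
                    if res["smiles"] in seen:
                        continue
                    seen.add(res["smiles"])
                    res["linker_index"] = li + 1
                    res["termini_indices"] = [t + 1 for t in assign]
                    products.append(res)
    return {"products": products, "n_invalid": n_invalid}


# -------------------------------------------------------------- descriptors

_DESC = dict(Descriptors.descList)


def _fingerprint_cols(mol, spec):
    names, vals = [], []
    for fp in spec:
        if fp["name"] == "maccs":
            bv = rdMolDescriptors.GetMACCSKeysFingerprint(mol)
            names += [f"maccs_{i}" for i in range(bv.GetNumBits())]
            vals += [float(b) for b in bv.ToBitString()]
        elif fp["name"] == "morgan":
            nb = int(fp.get("n_bits", 1024))
            bv = rdMolDescriptors.GetMorganFingerprintAsBitVect(
                mol, int(fp.get("radius", 2)), nBits=nb)
            names += [f"morgan_{i}" for i in range(nb)]
            vals += [float(b) for b in bv.ToBitString()]
        else:
            raise ValueError(f"unknown fingerprint: {fp['name']}")
    return names, vals


def op_descriptors(req):
    desc_names = req.get("descriptors", [])
    unknown = [d for d in desc_names if d not in _DESC]
    if unknown:
        raise ValueError(f"unknown descriptors: {unknown}")
    fp_spec = req.get("fingerprints", [])
    ids = req.get("ids") or req["smiles"]
    rows, colnames = [], None
    for s, lid in zip(req["smiles"], ids):
        mol = _mol(s, f"ligand {lid}")
        vals, names = [], []
        for d in desc_names:
            try:
                v = float(_DESC[d](mol))
            except Exception:
                v = float("nan")
            names.append(d)
            vals.append(v)
        fn, fv = _fingerprint_cols(mol, fp_spec)
        names += fn
        vals += fv
        if colnames is None:
            colnames = names
        rows.append(vals)
    return {"feature_names": colnames or [], "matrix": rows}


# --------------------------------------------------------------------- misc

def op_substructure(req):
    patt = _strip_dummies(_mol(req["query"], "query"))
    return {"match": [bool(_mol(s).HasSubstructMatch(patt))
                      for s in req["smiles"]]}


def op_embed3d(req):
    """ETKDG 3D coordinates; returns an SDF text block (fixture generation)."""
    from io import StringIO
    sio = StringIO()
    w = Chem.SDWriter(sio)
    for lig in req["ligands"]:
        mol = Chem.AddHs(_mol(lig["smiles"], lig["ligand_id"]))
        ps = AllChem.ETKDGv3()
        ps.randomSeed = int(req.get("seed", 2022))
        AllChem.EmbedMolecule(mol, ps)
        mol = Chem.RemoveHs(mol)
        mol.SetProp("_Name", lig["ligand_id"])
        w.write(mol)
    w.close()
    return {"sdf": sio.getvalue()}


def op_tsne(req):
    import numpy as np
    from sklearn.manifold import TSNE
    x = np.asarray(req["matrix"], dtype=float)
    perplexity = float(req.get("perplexity", 30))
    perplexity = min(perplexity, (x.shape[0] - 1) / 3.0)
    emb = TSNE(n_components=2, perplexity=perplexity, init="pca",
               random_state=int(req.get("seed", 0))).fit_transform(x)
    return {"coords": emb.tolist()}


OPS = {
    "canonicalize": op_canonicalize,
    "decompose": op_decompose,
    "enumerate": op_enumerate,
    "descriptors": op_descriptors,
    "substructure": op_substructure,
    "embed3d": op_embed3d,
    "tsne": op_tsne,
}


def main():
    req_path, res_path = sys.argv[1], sys.argv[2]
    with open(req_path) as fh:
        req = json.load(fh)
    try:
        res = OPS[req["op"]](req)
        res["ok"] = True
    except Exception as exc:  # surfaced as an R error
        res = {"ok": False, "error": f"{type(exc).__name__}: {exc}"}
    def _clean(o):  # strict JSON: non-finite floats become null
        if isinstance(o, float) and not math.isfinite(o):
            return None
        if isinstance(o, list):
            return [_clean(v) for v in o]
        if isinstance(o, dict):
            return {k: _clean(v) for k, v in o.items()}
        return o

    with open(res_path, "w") as fh:
        json.dump(_clean(res), fh, allow_nan=False)


if __name__ == "__main__":
    main()
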