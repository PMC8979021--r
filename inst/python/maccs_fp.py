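"""Compute 166-key MACCS fingerprints for SMILES read from stdin.

Input : TSV on stdin, two columns, no header: id <TAB> smiles
Output: TSV on stdout, one row per input row, columns:
          id, status ("ok"|"error"), canonical_smiles, bits
        where bits is a 166-character string of 0/1 (public MACCS keys
        1..166; the toolkit's unused key 0 is dropped). On parse failure
        status is "error", canonical_smiles holds a diagnostic and bits
        is empty.

Kept deliberately free of non-RDKit dependencies so it can run under any
Python that has RDKit importable.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import MACCSkeys

RDLogger.DisableLog("rdApp.*")


def main():
    out = sys.stdout
    for line in sys.stdin:
        line = line.rstrip("\n")
        if not line:
            continue
        parts = line.split("\t")
        if len(parts) < 2:
            out.write("%s\terror\tmalformed input row\t\n" % (parts[0] if parts else ""))
            continue
        mid, smiles = parts[0], parts[1]
        mol = Chem.MolFromSmiles(smiles)
        if mol is None:
            out.write("%s\terror\tunparseable SMILES: %s\t\n" % (mid, smiles))
            continue
        fp = MACCSkeys.GenMACCSKeys(mol)  # 167 bits, bit 0 always unset
        bits = "".join("1" if fp.GetBit(i) else "0" for i in range(1, 167))
        out.write("%s\tok\t%s\t%s\n" % (mid, Chem.MolToSmiles(mol), bits))
    out.flush()


if __name__ == "__main__":
    main()
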