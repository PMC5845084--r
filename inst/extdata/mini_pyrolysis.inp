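! Minimal ethane-pyrolysis style mechanism used by the tests.
! Every species carries its SMILES as an identifier comment.
ELEMENTS
C H
END
SPECIES
C2H6   ! CC
CH3    ! [CH3]
CH4    ! C
C2H5   ! [CH2]C  trailing-free-text-is-ignored
H      ! [H]
H2     ! [H][H]
C2H4   ! C=C
C3H7   ! [CH2]CC
END
REACTIONS
C2H6=CH3+CH3            1.0E16   0.0   90000
CH3+CH3(+M)=C2H6(+M)    1.0E13   0.0       0
  LOW / 1.0E10 0.0 0.0 /
CH3+C2H6=CH4+C2H5       1.0E12   0.0   11000
H+C2H6=H2+C2H5          1.0E14   0.0    9000
C2H5=C2H4+H             1.0E13   0.0   40000
C2H4+H=C2H5             1.0E13   0.0    1500
C2H5+H=C2H6             1.0E13   0.0       0
C2H4+CH3=C3H7           1.0E11   0.0    7000
END
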