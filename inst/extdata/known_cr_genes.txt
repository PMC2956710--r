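ACPP
ADAM2
AMACR
AMD1
ASAH1
DHCR24
FLNA
KLK3
KPNB1
PLA2G2A
RPL13A
RPL35A
RPL37A
RPL39
RPLP2
RPS20
STEAP2
TACC
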