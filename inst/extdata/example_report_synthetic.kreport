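100.00	10000	120	R	1	root
 72.40	7240	340	D	2	  Bacteria
 40.11	4011	60	G	1301	    Streptococcus
 22.05	2205	2205	S	1313	      Streptococcus pneumoniae
 10.00	1000	940	S	1318	      Streptococcus mitis
  0.60	60	60	S1	1310	        Streptococcus mitis B6
  8.30	830	20	G	724	    Haemophilus
  8.10	810	810	S	727	      Haemophilus influenzae
  4.20	420	420	S	2104	      Mycoplasmoides pneumoniae
  1.10	110	110	S	5476	      Candida albicans
  0.03	3	3	S	10376	      Human gammaherpesvirus 4
  0.02	2	2	S	1280	      Staphylococcus aureus
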