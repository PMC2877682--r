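name,group,ontario_count
Patel,South Asian,35984
Singh,South Asian,31820
Sharma,South Asian,10216
Kaur,South Asian,7462
Persaud,South Asian,6982
Sandhu,South Asian,6229
Grewal,South Asian,6044
Sidhu,South Asian,5862
Dhaliwal,South Asian,5209
Dhillon,South Asian,4847
Wong,Chinese,34567
Chan,Chinese,32692
Li,Chinese,27608
Chen,Chinese,25618
Wang,Chinese,22548
Liu,Chinese,18784
Zhang,Chinese,18003
Lam,Chinese,15910
Leung,Chinese,13696
Ho,Chinese,12830
Smith,General Population,91575
Brown,General Population,57222
Lee,General Population,49898
Wilson,General Population,43803
Martin,General Population,38878
Taylor,General Population,35746
Campbell,General Population,34551
Williams,General Population,34104
Thompson,General Population,33810
Jones,General Population,32644
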