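the
a
an
and
or
but
of
to
in
on
at
for
with
by
from
as
is
are
was
were
be
been
being
it
its
this
that
these
those
i
you
he
we
they
them
his
him
my
your
our
their
me
us
so
if
then
than
too
very
just
not
no
yes
do
does
did
have
has
had
will
would
can
could
should
rt
amp
via
about
into
over
under
after
before
what
when
where
who
why
how
all
any
some
more
most
other
such
only
also
now
out
up
down
here
there
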